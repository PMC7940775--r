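#' Define a behavioral award rule
#'
#' A rule is a predicate over one coded channel (or the mobility features):
#' a statistic, a comparator and a threshold, evaluated per day or per week.
#' For `window = "week"` the day-level predicate is applied to each day and
#' the rule is met when at least `min_days` days qualify.
#'
#' @param rule_id short unique identifier.
#' @param description human-readable description.
#' @param channel one of `"proximity"`, `"activity"`, `"speech"`,
#'   `"mobility"`.
#' @param statistic `"hours_in_state"` (count of hours coded `state`),
#'   `"speech_pct"` (daily speech count percentage), or
#'   `"fraction_outside"` (daily fraction of observed time outside home).
#' @param state hour state counted by `hours_in_state`, else `NA`.
#' @param comparator `">="` or `"<="`.
#' @param threshold non-negative numeric threshold for the day-level
#'   statistic.
#' @param window `"day"` or `"week"`.
#' @param min_days qualifying days required when `window = "week"`.
#' @return an object of class `award_rule`.
#' @export
award_rule <- function(rule_id, description, channel, statistic,
                       state = NA_character_, comparator = c(">=", "<="),
                       threshold = 1, window = c("day", "week"),
                       min_days = 1L) {
  channel <- match.arg(channel, c("proximity", "activity", "speech", "mobility"))
  statistic <- match.arg(statistic, c("hours_in_state", "speech_pct",
                                      "fraction_outside"))
  comparator <- match.arg(comparator)
  window <- match.arg(window)
  stopifnot(threshold >= 0, min_days >= 1)
  compatible <- switch(statistic,
    hours_in_state = channel %in% c("proximity", "activity", "speech"),
    speech_pct = channel == "speech",
    fraction_outside = channel == "mobility")
  if (!compatible) stop("statistic ", statistic, " incompatible with channel ", channel)
  if (statistic == "hours_in_state" && is.na(state)) {
    stop("hours_in_state rules need a state")
  }
  structure(list(rule_id = rule_id, description = description,
                 channel = channel, statistic = statistic, state = state,
                 comparator = comparator, threshold = threshold,
                 window = window, min_days = as.integer(min_days)),
            class = "award_rule")
}

#' Default behavioral-activation rule set
#'
#' Ships one rule per goal category: social interaction (speech present
#' during the day; hours together with the infant), daily routine (active
#' hours), and self-care/community engagement (left the home). All
#' thresholds are configurable by building your own rules.
#'
#' @param active_hours,together_hours day-level hour thresholds.
#' @return named list of `award_rule`s.
#' @export
default_award_rules <- function(active_hours = 4, together_hours = 8) {
  rules <- list(
    award_rule("speech_day", "Speech present in the environment during the day",
               "speech", "hours_in_state", state = "speech", threshold = 1),
    award_rule("active_day", paste0("At least ", active_hours, " active hours in the day"),
               "activity", "hours_in_state", state = "active",
               threshold = active_hours),
    award_rule("together_day", paste0("At least ", together_hours,
                                      " hours together with the infant"),
               "proximity", "hours_in_state", state = "together",
               threshold = together_hours),
    # fraction_outside > 0 expressed as >= epsilon (comparators are >=/<=)
    award_rule("left_home_day", "Left the home during the day",
               "mobility", "fraction_outside", threshold = 1e-9)
  )
  stats::setNames(rules, vapply(rules, `[[`, "", "rule_id"))
}

#' Default award message catalog
#'
#' Placeholder motivational card texts keyed by rule id; deployments supply
#' their own catalog.
#'
#' @return named character vector.
#' @export
default_award_messages <- function() {
  c(speech_day = "Great job! There was conversation around you today.",
    active_day = "Well done staying active today!",
    together_day = "Wonderful - you and your baby spent lots of time together.",
    left_home_day = "Nice! You got out of the house today.")
}

day_statistic <- function(rule, codes, mobility_row) {
  switch(rule$statistic,
    hours_in_state = sum(codes[[rule$channel]] == rule$state),
    speech_pct = attr(codes, "speech_pct"),
    fraction_outside = if (is.null(mobility_row) || nrow(mobility_row) == 0L) {
      NA_real_
    } else {
      mobility_row$fraction_outside_home[1]
    }
  )
}

day_satisfies <- function(rule, codes, mobility_row) {
  stat <- day_statistic(rule, codes, mobility_row)
  if (is.na(stat)) return(FALSE)
  if (rule$comparator == ">=") stat >= rule$threshold else stat <= rule$threshold
}

#' Evaluate award rules over coded days
#'
#' Emits one award per satisfied (rule, period): per qualifying day for
#' day-window rules, one per evaluated week for week-window rules (met when
#' at least `min_days` days qualify). Re-evaluating the same period never
#' duplicates awards. Rules referencing a channel absent from the inputs
#' (e.g. mobility rules without mobility features) are skipped and listed in
#' the `"skipped_rules"` attribute.
#'
#' @param codes_list list of `daily_codes`, one per day.
#' @param mobility optional data frame of daily [mobility_features()].
#' @param rules list of `award_rule`s, default [default_award_rules()].
#' @param messages named message catalog keyed by rule id.
#' @return data frame of awards (`participant_id`, `rule_id`, `period`,
#'   `message`) ordered by (period, rule_id).
#' @export
evaluate_rules <- function(codes_list, mobility = NULL,
                           rules = default_award_rules(),
                           messages = default_award_messages()) {
  if (inherits(codes_list, "daily_codes")) codes_list <- list(codes_list)
  dates <- vapply(codes_list, function(cd) format(attr(cd, "date")), character(1))
  pid <- if (length(codes_list)) attr(codes_list[[1]], "participant_id") else NA_character_
  out <- data.frame(participant_id = character(0), rule_id = character(0),
                    period = character(0), message = character(0))
  skipped <- character(0)
  for (rule in rules) {
    if (rule$channel == "mobility" &&
        (is.null(mobility) || !"fraction_outside_home" %in% names(mobility))) {
      warning("rule ", rule$rule_id, " skipped: mobility features unavailable")
      skipped <- c(skipped, rule$rule_id)
      next
    }
    sat <- vapply(seq_along(codes_list), function(i) {
      mrow <- if (is.null(mobility)) NULL else
        mobility[mobility$date == dates[i], , drop = FALSE]
      day_satisfies(rule, codes_list[[i]], mrow)
    }, logical(1))
    msg <- if (rule$rule_id %in% names(messages)) messages[[rule$rule_id]]
           else rule$description
    if (rule$window == "day") {
      if (any(sat)) {
        out <- rbind(out, data.frame(participant_id = pid,
                                     rule_id = rule$rule_id,
                                     period = dates[sat], message = msg))
      }
    } else if (sum(sat) >= rule$min_days && length(dates)) {
      out <- rbind(out, data.frame(participant_id = pid,
                                   rule_id = rule$rule_id,
                                   period = paste0("week:", min(dates)),
                                   message = msg))
    }
  }
  out <- out[!duplicated(out[c("participant_id", "rule_id", "period")]), ,
             drop = FALSE]
  out <- out[order(out$period, out$rule_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped_rules") <- skipped
  out
}

#' Create a weekly counseling goal
#'
#' Goals are recorded during the counseling session; a goal may be linked to
#' an award rule, in which case its progress can be evaluated from the
#' passive data.
#'
#' @param participant_id participant code.
#' @param week_index 1-based week number within the intervention.
#' @param text free-text goal as recorded in session.
#' @param rule_id linked `award_rule` id, or `NA` for free-text goals.
#' @return an object of class `weekly_goal` with status `"set"`.
#' @export
weekly_goal <- function(participant_id, week_index, text, rule_id = NA_character_) {
  structure(list(participant_id = participant_id,
                 week_index = as.integer(week_index), text = text,
                 rule_id = rule_id, status = "set"),
            class = "weekly_goal")
}

#' Evaluate a weekly goal against a week of coded days
#'
#' A goal linked to a rule transitions `set` to `met` or `unmet` depending
#' on whether the rule (forced to a week window) is satisfied over the
#' supplied days; an unlinked goal is returned unchanged.
#'
#' @param goal a `weekly_goal`.
#' @inheritParams evaluate_rules
#' @return the goal with updated `status`.
#' @export
goal_progress <- function(goal, codes_list, mobility = NULL,
                          rules = default_award_rules()) {
  stopifnot(inherits(goal, "weekly_goal"))
  if (is.na(goal$rule_id)) return(goal)
  rule <- NULL
  for (r in rules) if (r$rule_id == goal$rule_id) rule <- r
  if (is.null(rule)) stop("goal links unknown rule ", goal$rule_id)
  rule$window <- "week"
  awards <- suppressWarnings(
    evaluate_rules(codes_list, mobility, rules = list(rule), messages = character(0))
  )
  goal$status <- if (nrow(awards) > 0L) "met" else "unmet"
  goal
}

#' @export
print.weekly_goal <- function(x, ...) {
  cat("<weekly_goal>", x$participant_id, "week", x$week_index, "-",
      x$status, "\n  ", x$text, "\n")
  invisible(x)
}

#' Read award rules from a YAML config file
#'
#' Each top-level list entry supplies the [award_rule()] fields.
#'
#' @param path YAML file.
#' @return named list of `award_rule`s.
#' @export
read_rules_config <- function(path) {
  raw <- yaml::read_yaml(path)
  rules <- lapply(raw, function(r) do.call(award_rule, r))
  stats::setNames(rules, vapply(rules, `[[`, "", "rule_id"))
}
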