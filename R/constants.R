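# Shared vocabulary for the three-task IPL study design.

#' Task and condition vocabulary
#'
#' The experimental design crosses three cognitive tasks (attentional
#' reorienting, lexical decision / semantics, perspective taking / social
#' cognition), each with one target condition isolating the process of
#' interest and one matched control condition; the attention task additionally
#' contains response-free catch trials.
#'
#' @format `ipl_tasks()` returns the three task names in canonical order;
#'   `ipl_conditions(task)` the condition set of one task;
#'   `ipl_target_condition(task)` its target condition;
#'   `ipl_subregions()` the four subregion names;
#'   `ipl_networks()` the seven large-scale network names.
#' @name vocabulary
NULL

.TASKS <- c("attention", "semantics", "social")

.CONDITIONS <- list(
  attention = c("invalid", "valid", "catch"),
  semantics = c("word", "pseudoword"),
  social    = c("false_belief", "true_belief")
)

.TARGET <- c(attention = "invalid", semantics = "word", social = "false_belief")

# per-run trial counts of the event-related design
.DESIGN_COUNTS <- list(
  attention = c(invalid = 8L, valid = 30L, catch = 2L),
  semantics = c(word = 20L, pseudoword = 20L),
  social    = c(false_belief = 3L, true_belief = 3L)
)

# mean / sd / minimum inter-trial interval (s) used for jittered onsets
.ITI <- list(
  attention = c(mean = 3.2, sd = 1.41, min = 2),
  semantics = c(mean = 3.8, sd = 1.7, min = 2),
  social    = c(mean = 3.8, sd = 1.7, min = 2)
)

.SUBREGIONS <- c("L-ant", "L-post", "R-ant", "R-post")
.FEATURE_COLS <- c("L_ant", "L_post", "R_ant", "R_post")

.NETWORKS <- c("VIS", "SMN", "DAN", "VAN", "LIM", "FPN", "DMN")

#' @rdname vocabulary
#' @export
ipl_tasks <- function() .TASKS

#' @rdname vocabulary
#' @param task one of `"attention"`, `"semantics"`, `"social"`
#' @export
ipl_conditions <- function(task) {
  .CONDITIONS[[match.arg(task, .TASKS)]]
}

#' @rdname vocabulary
#' @export
ipl_target_condition <- function(task) {
  unname(.TARGET[match.arg(task, .TASKS)])
}

#' @rdname vocabulary
#' @export
ipl_subregions <- function() .SUBREGIONS

#' @rdname vocabulary
#' @export
ipl_networks <- function() .NETWORKS
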