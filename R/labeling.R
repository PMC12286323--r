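#' Label trials under the three labeling strategies
#'
#' Three strategies assign a comprehension class to each trial:
#' \describe{
#'   \item{strategy 1}{binary, from multiple-choice correctness:
#'     correct -> `understood`, incorrect -> `not_understood`; trials with
#'     a blank answer are excluded.}
#'   \item{strategy 2}{three classes from the self-assessment score:
#'     SAS 1-4 -> `class1` (not understood), 5-7 -> `class2` (a little
#'     understood), 8-10 -> `class3` (understood); missing SAS excluded.}
#'   \item{strategy 3}{double-validated binary labels requiring agreement
#'     of both criteria: `understood` iff SAS >= 8 AND the answer was
#'     correct; `not_understood` iff SAS <= 4 AND the answer was incorrect.
#'     Middle SAS (5-7), disagreements between the two criteria, and
#'     missing fields are excluded. The intersection minimizes labels
#'     driven by lucky or careless answers.}
#' }
#'
#' @param ts a [nirs_trial_set()]
#' @param strategy 1, 2 or 3
#' @return data frame with columns `trial_id`, `label` (factor), `strategy`;
#'   excluded trials are reported in the `"exclusions"` attribute as a data
#'   frame of `trial_id`, `reason`
#' @export
label_trials <- function(ts, strategy) {
  stopifnot(inherits(ts, "nirs_trial_set"), strategy %in% 1:3)
  meta <- trial_metadata(ts)
  lab <- character(nrow(meta))
  reason <- character(nrow(meta))
  if (strategy == 1) {
    lab[which(meta$mc_correct %in% TRUE)] <- "understood"
    lab[which(meta$mc_correct %in% FALSE)] <- "not_understood"
    reason[is.na(meta$mc_correct)] <- "mc_correct missing"
    levels <- c("not_understood", "understood")
  } else if (strategy == 2) {
    lab[which(meta$sas >= 1 & meta$sas <= 4)] <- "class1"
    lab[which(meta$sas >= 5 & meta$sas <= 7)] <- "class2"
    lab[which(meta$sas >= 8 & meta$sas <= 10)] <- "class3"
    reason[is.na(meta$sas)] <- "sas missing"
    levels <- c("class1", "class2", "class3")
  } else {
    und <- which(meta$sas >= 8 & meta$mc_correct %in% TRUE)
    not <- which(meta$sas <= 4 & meta$mc_correct %in% FALSE)
    lab[und] <- "understood"
    lab[not] <- "not_understood"
    excl <- lab == ""
    reason[excl & is.na(meta$sas)] <- "sas missing"
    reason[excl & reason == "" & is.na(meta$mc_correct)] <- "mc_correct missing"
    reason[excl & reason == "" & meta$sas >= 5 & meta$sas <= 7] <- "sas in 5..7"
    reason[excl & reason == ""] <- "sas and mc_correct disagree"
    levels <- c("not_understood", "understood")
  }
  keep <- lab != ""
  out <- data.frame(trial_id = meta$trial_id[keep],
                    label = factor(lab[keep], levels = levels),
                    strategy = strategy, stringsAsFactors = FALSE)
  attr(out, "exclusions") <- data.frame(
    trial_id = meta$trial_id[!keep],
    reason = ifelse(reason[!keep] == "", "unlabelable", reason[!keep]),
    stringsAsFactors = FALSE)
  out
}

#' @rdname label_trials
#' @export
label_strategy1 <- function(ts) label_trials(ts, 1)

#' @rdname label_trials
#' @export
label_strategy2 <- function(ts) label_trials(ts, 2)

#' @rdname label_trials
#' @export
label_strategy3 <- function(ts) label_trials(ts, 3)

#' Write a labeling exclusion report
#'
#' @param labeled result of [label_trials()]
#' @param path CSV file path
#' @return `path`, invisibly
#' @export
write_exclusions <- function(labeled, path) {
  write.csv(attr(labeled, "exclusions"), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
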