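#' Construct a single fNIRS trial
#'
#' A trial is the multi-channel signal segment recorded while one text was
#' read (between the onset marker S1 and the offset marker S2), together
#' with its behavioural metadata: the participant's 1-10 self-assessment
#' score (SAS) and whether the multiple-choice question was answered
#' correctly. Either metadata field may be absent (`NA`): participants were
#' allowed to leave answers blank.
#'
#' @param trial_id unique identifier (string)
#' @param participant_id participant identifier (string)
#' @param chromophore one of `"OxyHb"`, `"DeoxyHb"`, `"TotalHb"`
#' @param data numeric matrix, channels x samples, finite
#' @param fs sampling frequency in Hz
#' @param sas integer self-assessment score in 1..10, or `NA`
#' @param mc_correct logical multiple-choice correctness, or `NA`
#' @param markers length-2 integer vector `c(s1, s2)` of 0-based sample
#'   indices with `s1 < s2`, both within `[0, n_samples)`; the trial data
#'   are taken over the half-open interval `[s1, s2)`
#' @return an object of class `nirs_trial`
#' @export
nirs_trial <- function(trial_id, participant_id, chromophore, data, fs,
                       sas = NA_integer_, mc_correct = NA,
                       markers = c(0L, ncol(data) - 1L)) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (!all(is.finite(data)))
    stop("trial '", trial_id, "': data contains non-finite values")
  chromophore <- match.arg(chromophore, c("OxyHb", "DeoxyHb", "TotalHb"))
  if (!is.na(sas)) {
    sas <- as.integer(sas)
    if (sas < 1L || sas > 10L)
      stop("trial '", trial_id, "': sas must be in 1..10, got ", sas)
  }
  if (!is.na(mc_correct) && !is.logical(mc_correct))
    stop("trial '", trial_id, "': mc_correct must be logical or NA")
  markers <- as.integer(markers)
  if (length(markers) != 2L || markers[1] >= markers[2] ||
      markers[1] < 0L || markers[2] >= ncol(data))
    stop("trial '", trial_id, "': markers must satisfy 0 <= S1 < S2 < n_samples")
  structure(list(trial_id = as.character(trial_id),
                 participant_id = as.character(participant_id),
                 chromophore = chromophore,
                 data = data, fs = as.numeric(fs),
                 sas = if (is.na(sas)) NA_integer_ else sas,
                 mc_correct = if (is.na(mc_correct)) NA else as.logical(mc_correct),
                 markers = markers),
            class = "nirs_trial")
}

#' @export
print.nirs_trial <- function(x, ...) {
  cat(sprintf("<nirs_trial %s> participant %s, %s, %d ch x %d samples @ %.4f Hz\n",
              x$trial_id, x$participant_id, x$chromophore,
              nrow(x$data), ncol(x$data), x$fs))
  cat(sprintf("  S1=%d S2=%d, sas=%s, mc_correct=%s\n",
              x$markers[1], x$markers[2], x$sas, x$mc_correct))
  invisible(x)
}

#' Construct a trial set
#'
#' An ordered collection of trials sharing channel layout and sampling
#' frequency. Trial ids must be unique.
#'
#' @param trials list of [nirs_trial()] objects
#' @param channel_names character vector of channel labels; defaults to
#'   `CH1..CHn` from the first trial
#' @return an object of class `nirs_trial_set`
#' @export
nirs_trial_set <- function(trials, channel_names = NULL) {
  stopifnot(is.list(trials))
  if (length(trials)) {
    stopifnot(all(vapply(trials, inherits, TRUE, "nirs_trial")))
    nch <- vapply(trials, function(t) nrow(t$data), 0L)
    fs <- vapply(trials, function(t) t$fs, 0)
    if (length(unique(nch)) != 1L)
      stop("all trials must share the channel count; saw ",
           paste(unique(nch), collapse = ", "))
    if (length(unique(fs)) != 1L)
      stop("all trials must share the sampling frequency")
    if (is.null(channel_names)) channel_names <- paste0("CH", seq_len(nch[1]))
    if (length(channel_names) != nch[1])
      stop("channel_names length must equal the channel count")
    ids <- vapply(trials, function(t) t$trial_id, "")
    if (anyDuplicated(ids)) stop("duplicate trial ids: ",
                                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
    names(trials) <- ids
  } else if (is.null(channel_names)) channel_names <- character()
  structure(list(trials = trials, channel_names = channel_names),
            class = "nirs_trial_set")
}

#' @export
print.nirs_trial_set <- function(x, ...) {
  cat(sprintf("<nirs_trial_set> %d trials, %d channels\n",
              length(x$trials), length(x$channel_names)))
  invisible(x)
}

#' @export
length.nirs_trial_set <- function(x) length(x$trials)

#' Tabulate trial metadata
#'
#' @param ts a [nirs_trial_set()]
#' @return data frame with one row per trial:
#'   trial_id, participant_id, chromophore, sas, mc_correct, s1, s2, fs,
#'   n_samples
#' @export
trial_metadata <- function(ts) {
  stopifnot(inherits(ts, "nirs_trial_set"))
  do.call(rbind, c(lapply(ts$trials, function(t)
    data.frame(trial_id = t$trial_id, participant_id = t$participant_id,
               chromophore = t$chromophore,
               sas = t$sas, mc_correct = t$mc_correct,
               s1 = t$markers[1], s2 = t$markers[2], fs = t$fs,
               n_samples = ncol(t$data), stringsAsFactors = FALSE)),
    list(make.row.names = FALSE)))
}

fmt_full <- function(m) {
  # full round-trip precision, one row per channel, comma delimited
  apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
}

#' Write a trial set to a directory
#'
#' Layout: one header-less CSV matrix per trial (`<trial_id>.csv`, rows =
#' channels) plus a `metadata.csv` table keyed by trial_id. Numeric values
#' are serialized at full precision so that a read/write round trip is
#' bit-exact. Empty metadata cells encode absent sas / mc_correct.
#'
#' @param ts a [nirs_trial_set()]
#' @param path directory (created if missing)
#' @return `path`, invisibly
#' @export
write_trials <- function(ts, path) {
  stopifnot(inherits(ts, "nirs_trial_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  meta <- data.frame(trial_id = character(), participant_id = character(),
                     chromophore = character(), sas = integer(),
                     mc_correct = logical(), s1 = integer(), s2 = integer(),
                     fs = numeric(), stringsAsFactors = FALSE)
  for (t in ts$trials) {
    writeLines(fmt_full(t$data), file.path(path, paste0(t$trial_id, ".csv")))
    meta <- rbind(meta, data.frame(
      trial_id = t$trial_id, participant_id = t$participant_id,
      chromophore = t$chromophore, sas = t$sas, mc_correct = t$mc_correct,
      s1 = t$markers[1], s2 = t$markers[2], fs = t$fs,
      stringsAsFactors = FALSE))
  }
  write.csv(meta, file.path(path, "metadata.csv"), row.names = FALSE,
            quote = FALSE, na = "")
  if (length(ts$trials) == 0L)  # header-only metadata for an empty set
    writeLines("trial_id,participant_id,chromophore,sas,mc_correct,s1,s2,fs",
               file.path(path, "metadata.csv"))
  invisible(path)
}

#' Read a trial set from a directory
#'
#' Inverse of [write_trials()]. Trials with empty sas / mc_correct cells
#' load with those fields absent; they are excluded later by labeling
#' strategies that need them, not rejected here.
#'
#' @param path directory containing `metadata.csv` and one matrix CSV per
#'   trial
#' @return a [nirs_trial_set()]
#' @export
read_trials <- function(path) {
  meta_file <- file.path(path, "metadata.csv")
  if (!file.exists(meta_file)) stop("no metadata.csv under ", path)
  meta <- read.csv(meta_file, stringsAsFactors = FALSE,
                   colClasses = c(trial_id = "character",
                                  participant_id = "character",
                                  chromophore = "character"))
  mats <- sub("\\.csv$", "", setdiff(basename(list.files(path, "\\.csv$")),
                                     "metadata.csv"))
  missing_mat <- setdiff(meta$trial_id, mats)
  if (length(missing_mat))
    stop("metadata rows without matrix files: ",
         paste(missing_mat, collapse = ", "))
  orphan <- setdiff(mats, meta$trial_id)
  if (length(orphan))
    stop("matrix files without metadata rows: ", paste(orphan, collapse = ", "))
  trials <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    id <- meta$trial_id[i]
    lines <- readLines(file.path(path, paste0(id, ".csv")))
    rows <- strsplit(lines, ",", fixed = TRUE)
    ncols <- lengths(rows)
    if (length(unique(ncols)) != 1L)
      stop("trial '", id, "': ragged matrix (row lengths ",
           paste(unique(ncols), collapse = ", "), ")")
    vals <- suppressWarnings(lapply(rows, as.numeric))
    bad <- which(vapply(vals, anyNA, TRUE))
    if (length(bad))
      stop("trial '", id, "': non-numeric cell in row ", bad[1])
    m <- do.call(rbind, vals)
    trials[[i]] <- nirs_trial(
      trial_id = id, participant_id = meta$participant_id[i],
      chromophore = meta$chromophore[i], data = m, fs = meta$fs[i],
      sas = meta$sas[i],
      mc_correct = if (is.na(meta$mc_correct[i])) NA else as.logical(meta$mc_correct[i]),
      markers = c(meta$s1[i], meta$s2[i]))
  }
  nirs_trial_set(trials)
}

#' Total hemoglobin trial from an oxy / deoxy pair
#'
#' TotalHb is the elementwise sum of the OxyHb and DeoxyHb
#' concentration-change signals (the standard fNIRS convention).
#'
#' @param oxy,deoxy [nirs_trial()]s sharing trial_id, shape, fs and markers,
#'   with chromophores OxyHb and DeoxyHb respectively
#' @return a TotalHb [nirs_trial()]
#' @export
total_hb <- function(oxy, deoxy) {
  stopifnot(inherits(oxy, "nirs_trial"), inherits(deoxy, "nirs_trial"))
  if (oxy$chromophore != "OxyHb" || deoxy$chromophore != "DeoxyHb")
    stop("total_hb expects (OxyHb, DeoxyHb) in that order")
  if (oxy$trial_id != deoxy$trial_id)
    stop("trial id mismatch: ", oxy$trial_id, " vs ", deoxy$trial_id)
  if (!identical(dim(oxy$data), dim(deoxy$data)))
    stop("trial '", oxy$trial_id, "': shape mismatch between chromophores")
  if (oxy$fs != deoxy$fs || !identical(oxy$markers, deoxy$markers))
    stop("trial '", oxy$trial_id, "': fs/marker mismatch between chromophores")
  out <- oxy
  out$chromophore <- "TotalHb"
  out$data <- oxy$data + deoxy$data
  out
}
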