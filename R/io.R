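#' @name behavior_io
#' @title Read and write behavior trial tables
#'
#' @description Trial tables are tab-separated, UTF-8, '.' decimal, with a
#' header. Required columns: `trial`, `block`, `onset_s`, `x`, `y`,
#' `true_category`; optional: `response`, `correct`, `rt`. Reading
#' validates the schema (missing columns, non-numeric fields, bad category
#' codes, non-increasing onsets) with errors that name the offending
#' column or row.
NULL

.BEHAVIOR_REQUIRED <- c("trial", "block", "onset_s", "x", "y",
                        "true_category")
.BEHAVIOR_OPTIONAL <- c("response", "correct", "rt")

#' @rdname behavior_io
#' @param behavior A behavior data.frame.
#' @param path File path.
#' @export
write_behavior <- function(behavior, path) {
  miss <- setdiff(.BEHAVIOR_REQUIRED, names(behavior))
  if (length(miss)) {
    stop("behavior table missing column(s): ", paste(miss, collapse = ", "))
  }
  cols <- c(.BEHAVIOR_REQUIRED,
            intersect(.BEHAVIOR_OPTIONAL, names(behavior)))
  write.table(behavior[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname behavior_io
#' @export
read_behavior <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
  miss <- setdiff(.BEHAVIOR_REQUIRED, names(df))
  if (length(miss)) {
    stop(sprintf("behavior file '%s' missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  }
  unknown <- setdiff(names(df), c(.BEHAVIOR_REQUIRED, .BEHAVIOR_OPTIONAL))
  if (length(unknown)) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  }
  for (col in c("trial", "block", "onset_s", "x", "y")) {
    if (!is.numeric(df[[col]])) {
      stop(sprintf("column '%s' must be numeric", col))
    }
  }
  bad <- which(!df$true_category %in% .CATEGORIES)
  if (length(bad)) {
    stop(sprintf("invalid true_category at row %d", bad[1]))
  }
  if ("response" %in% names(df)) {
    bad <- which(!(df$response %in% .CATEGORIES | is.na(df$response) |
                     df$response == ""))
    if (length(bad)) stop(sprintf("invalid response at row %d", bad[1]))
    df$response[df$response == ""] <- NA_character_
  }
  if ("correct" %in% names(df)) df$correct <- as.logical(df$correct)
  if (any(diff(df$onset_s) <= 0)) {
    stop(sprintf("onsets not strictly increasing at row %d",
                 which(diff(df$onset_s) <= 0)[1] + 1L))
  }
  df
}

#' Read and write model parameters as JSON
#'
#' @param params A [model_params()] (writing) or file path (reading).
#' @param path File path.
#' @return `read_params()` returns a [model_params()].
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_params(rb_lr = p$rb_lr, ii_lr = p$ii_lr, ps_lr = p$ps_lr,
               ps_init = p$ps_init, dm_noise = p$dm_noise,
               feedback_model = p$feedback_model,
               single_lr_mode = isTRUE(p$single_lr_mode))
}

#' Read and write group accuracy summaries
#'
#' Tab-separated with columns `condition`, `block`, `mean_acc`, `sd_acc`.
#'
#' @param summary A `group_summary` data.frame.
#' @param path File path.
#' @export
write_summary <- function(summary, path) {
  stopifnot(all(c("condition", "block", "mean_acc", "sd_acc") %in%
                  names(summary)))
  write.table(as.data.frame(summary), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
  miss <- setdiff(c("condition", "block", "mean_acc", "sd_acc"), names(df))
  if (length(miss)) {
    stop("summary file missing column(s): ", paste(miss, collapse = ", "))
  }
  class(df) <- c("group_summary", "data.frame")
  df
}

#' Write a model-based events table
#'
#' One row per trial in an events-file layout whose first two columns are
#' `onset` and `duration` in seconds (stimulus onset; duration is the
#' stimulus presentation time), followed by the model-derived trial labels
#' used to build condition regressors: `trial_type` (winner x correctness,
#' e.g. `"RB_correct"`), `competition_class`, `off_system_correct`, the two
#' system probabilities, the response and its correctness.
#'
#' @param trace A simulated or replayed trial table containing `onset_s`,
#'   `winner` (or `responsible`), `p_a_rb`, `p_a_ii`, `response`,
#'   `correct`, `true_category`.
#' @param path File path.
#' @param timing A [timing_config()] supplying the stimulus duration.
#' @param threshold Competition-confidence cut.
#' @return The events data.frame, invisibly written to `path`.
#' @export
write_events <- function(trace, path, timing = timing_config(),
                         threshold = 0.75) {
  stopifnot(all(c("onset_s", "p_a_rb", "p_a_ii", "response", "correct",
                  "true_category") %in% names(trace)))
  tags <- tag_off_system(trace, threshold = threshold)
  events <- data.frame(
    onset = trace$onset_s,
    duration = timing$stimulus_ms / 1000,
    trial_type = paste0(tags$winner, "_",
                        ifelse(trace$correct, "correct", "incorrect")),
    competition_class = tags$competition_class,
    off_system_correct = tags$off_system_correct,
    p_a_rb = trace$p_a_rb,
    p_a_ii = trace$p_a_ii,
    response = trace$response,
    correct = trace$correct,
    stringsAsFactors = FALSE
  )
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(events)
}

#' Specification for a synthetic cohort
#'
#' Describes a simulated experiment standing in for a human study: a
#' number of subjects per condition, the generating model parameters
#' (optionally jittered per subject on the log scale to create individual
#' differences in learning rates), the category structures for the two
#' conditions, and a master seed from which every subject's sequence and
#' session seeds derive.
#'
#' With `paired = TRUE` the condition counts are ignored in favour of
#' `n_paired` subjects who each complete one RB and one II session with
#' the same parameters; their behavior entries are two-table lists
#' suitable for joint fitting with [fit_individual()], the design used
#' for parameter-recovery studies (both learning rates identified per
#' subject).
#'
#' @param n_rb,n_ii Subjects in the RB and II conditions
#'   (single-condition design).
#' @param paired If `TRUE`, generate `n_paired` two-session subjects
#'   instead of single-condition subjects.
#' @param n_paired Number of two-condition subjects when `paired = TRUE`.
#' @param n_sessions Sessions per condition per subject in the paired
#'   design. Likelihood information about the learning rates is
#'   concentrated in each session's early learning transient, so several
#'   sessions per condition sharpen individual estimates considerably.
#' @param params Generating [model_params()].
#' @param structures Named list (`RB`, `II`) of [make_structure()] objects.
#' @param lr_jitter Half-width of the uniform log-scale jitter applied to
#'   each subject's `rb_lr` and `ii_lr` (0 = all subjects identical).
#' @param master_seed Integer master seed.
#' @param n_trials,block_size Session design.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_rb = 17, n_ii = 17, params = model_params(),
                        structures = list(RB = make_structure("RB"),
                                          II = make_structure("II")),
                        lr_jitter = 0.8, master_seed = 1,
                        n_trials = 320, block_size = 80,
                        paired = FALSE, n_paired = 20, n_sessions = 1) {
  stopifnot(n_rb >= 0, n_ii >= 0, n_rb + n_ii >= 1,
            inherits(params, "model_params"), lr_jitter >= 0,
            all(c("RB", "II") %in% names(structures)),
            isTRUE(paired) || isFALSE(paired), n_paired >= 1,
            n_sessions >= 1)
  .assert_seed(master_seed)
  structure(
    list(n_rb = n_rb, n_ii = n_ii, params = params,
         structures = structures, lr_jitter = lr_jitter,
         master_seed = master_seed, n_trials = n_trials,
         block_size = block_size, paired = paired, n_paired = n_paired,
         n_sessions = n_sessions),
    class = "cohort_spec"
  )
}

#' Generate a synthetic behavioral cohort
#'
#' Simulates one session per subject under the (per-subject jittered)
#' generating parameters and returns behavior tables plus a ground-truth
#' manifest recording each subject's true parameters and seeds, so the
#' cohort can be regenerated exactly and used for parameter-recovery
#' studies.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional directory; when given, one `sub-XX.tsv` behavior
#'   file per subject plus `manifest.tsv` are written there.
#' @return A list with `behavior` (named list of behavior data.frames) and
#'   `manifest` (data.frame: subject, condition, seeds and true
#'   parameters).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  paired <- isTRUE(spec$paired)
  conditions <- if (paired) rep("both", spec$n_paired)
                else c(rep("RB", spec$n_rb), rep("II", spec$n_ii))
  n <- length(conditions)
  behavior <- vector("list", n)
  manifest <- vector("list", n)
  for (i in seq_len(n)) {
    seq_seed <- .run_seed(spec$master_seed, 11, i)
    jit_seed <- .run_seed(spec$master_seed, 12, i)
    ses_seed <- .run_seed(spec$master_seed, 13, i)
    set.seed(jit_seed)
    p <- spec$params
    if (spec$lr_jitter > 0) {
      p <- model_params(
        rb_lr = p$rb_lr * exp(runif(1, -spec$lr_jitter, spec$lr_jitter)),
        ii_lr = p$ii_lr * exp(runif(1, -spec$lr_jitter, spec$lr_jitter)),
        ps_lr = p$ps_lr, ps_init = p$ps_init, dm_noise = p$dm_noise,
        feedback_model = p$feedback_model,
        single_lr_mode = p$single_lr_mode
      )
    }
    one_session <- function(condition, seq_seed, ses_seed) {
      sq <- generate_sequence(spec$structures[[condition]],
                              spec$n_trials, spec$block_size,
                              seed = seq_seed)
      res <- run_session(p, sq, seed = ses_seed)
      beh <- res$trace[, c("trial", "block", "x", "y", "true_category",
                           "response", "correct")]
      beh$onset_s <- sq$onset_s
      beh[, c("trial", "block", "onset_s", "x", "y", "true_category",
              "response", "correct")]
    }
    id <- sprintf("sub-%02d", i)
    if (paired) {
      n_ses <- if (is.null(spec$n_sessions)) 1L else spec$n_sessions
      tabs <- list()
      for (s in seq_len(n_ses)) {
        off <- 10L * (s - 1L) # distinct seed lanes per session number
        tabs[[sprintf("RB%d", s)]] <-
          one_session("RB", .run_seed(spec$master_seed, 11 + off, i),
                      .run_seed(spec$master_seed, 13 + off, i))
        tabs[[sprintf("II%d", s)]] <-
          one_session("II", .run_seed(spec$master_seed, 14 + off, i),
                      .run_seed(spec$master_seed, 15 + off, i))
      }
      behavior[[i]] <- tabs
    } else {
      behavior[[i]] <- one_session(conditions[i], seq_seed, ses_seed)
    }
    names(behavior)[i] <- id
    manifest[[i]] <- data.frame(
      subject = id, condition = conditions[i],
      sequence_seed = seq_seed, session_seed = ses_seed,
      rb_lr = p$rb_lr, ii_lr = p$ii_lr, ps_lr = p$ps_lr,
      ps_init = p$ps_init, dm_noise = p$dm_noise,
      feedback_model = p$feedback_model,
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, manifest)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (id in names(behavior)) {
      if (paired) {
        for (cond in names(behavior[[id]])) {
          write_behavior(behavior[[id]][[cond]],
                         file.path(dir, sprintf("%s_%s.tsv", id, cond)))
        }
      } else {
        write_behavior(behavior[[id]], file.path(dir, paste0(id, ".tsv")))
      }
    }
    write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  }
  list(behavior = behavior, manifest = manifest)
}
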