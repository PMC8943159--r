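#' Default block layout for the face-name paradigm
#'
#' One run: a 5-s fixation block, then novelty and repetition blocks of 7
#' trials (4.75 s each, padded with jittered fixation to 40 s per block),
#' each block type shown twice and alternated with 25-s fixation blocks, and
#' a closing 5-s fixation. The scheduled durations sum to
#' 5 + 40 + 25 + 40 + 25 + 40 + 25 + 40 + 5 = 245 s (4 min 5 s).
#'
#' @param n_trials Trials per task block.
#' @param trial_duration_s Stimulus duration per trial, seconds.
#' @param block_duration_s Total task-block duration including jitter padding.
#' @param fix_edge_s Fixation at run start and end.
#' @param fix_between_s Fixation between task blocks.
#' @param block_order Condition sequence of the task blocks.
#' @return A `block_spec` list consumed by [make_task_design()].
#' @export
default_block_spec <- function(n_trials = 7, trial_duration_s = 4.75,
                               block_duration_s = 40, fix_edge_s = 5,
                               fix_between_s = 25,
                               block_order = c("novelty", "repetition",
                                               "novelty", "repetition")) {
  structure(list(n_trials = n_trials, trial_duration_s = trial_duration_s,
                 block_duration_s = block_duration_s, fix_edge_s = fix_edge_s,
                 fix_between_s = fix_between_s, block_order = block_order),
            class = "block_spec")
}

# Scheduled run duration implied by a block spec, in seconds.
scheduled_duration <- function(spec) {
  nb <- length(spec$block_order)
  2 * spec$fix_edge_s + nb * spec$block_duration_s +
    max(0, nb - 1) * spec$fix_between_s
}

#' Generate per-run task designs for a two-condition block paradigm
#'
#' Lays out the block schedule of `block_spec` on a TR grid and builds the
#' binary condition indicator series `x1` (novelty) and `x2` (repetition).
#' Trial onsets are snapped to the nearest TR sample. The per-trial jitter
#' padding (the slack between `n_trials * trial_duration_s` and the block
#' duration) is spread uniformly across the inter-trial gaps; with a seed it
#' is randomized per run. Runs shorter than `n_volumes * tr` are padded with
#' trailing fixation (the default 245-s schedule inside 127 volumes at
#' TR 2 s leaves 9 s of trailing fixation).
#'
#' @param tr_seconds Repetition time (sample spacing), seconds.
#' @param n_runs Number of runs to generate.
#' @param block_spec A [default_block_spec()] list.
#' @param n_volumes Volumes per run.
#' @param jitter_seed Optional integer; when given, the jitter padding is
#'   drawn uniformly at random (summing to the block slack) instead of split
#'   evenly.
#' @return A list of `task_design` objects, each with `tr_seconds`,
#'   `n_volumes`, indicator series `x1`, `x2`, an `events` data frame
#'   (trial_type, onset, duration) and `run_index`.
#' @export
make_task_design <- function(tr_seconds = 2, n_runs = 6,
                             block_spec = default_block_spec(),
                             n_volumes = 127, jitter_seed = NULL) {
  dur <- scheduled_duration(block_spec)
  run_len <- n_volumes * tr_seconds
  if (dur > run_len)
    stop("configuration error: scheduled block layout (", dur,
         " s) overflows the run (", run_len, " s) by ", dur - run_len, " s")
  slack <- block_spec$block_duration_s -
    block_spec$n_trials * block_spec$trial_duration_s
  if (slack < -1e-9)
    stop("configuration error: trials (",
         block_spec$n_trials * block_spec$trial_duration_s,
         " s) overflow the task block (", block_spec$block_duration_s,
         " s) by ", -slack, " s")
  lapply(seq_len(n_runs), function(run) {
    gaps <- if (is.null(jitter_seed)) {
      rep(slack / block_spec$n_trials, block_spec$n_trials)
    } else with_seed(child_seed(jitter_seed, run), {
      u <- stats::runif(block_spec$n_trials)
      slack * u / sum(u)
    })
    events <- list()
    t0 <- block_spec$fix_edge_s
    for (b in seq_along(block_spec$block_order)) {
      cond <- block_spec$block_order[b]
      tt <- t0
      for (k in seq_len(block_spec$n_trials)) {
        events[[length(events) + 1L]] <-
          data.frame(trial_type = cond, onset = tt,
                     duration = block_spec$trial_duration_s)
        tt <- tt + block_spec$trial_duration_s + gaps[k]
      }
      t0 <- t0 + block_spec$block_duration_s +
        if (b < length(block_spec$block_order)) block_spec$fix_between_s else 0
    }
    events <- if (length(events)) do.call(rbind, events)
      else data.frame(trial_type = character(), onset = numeric(),
                      duration = numeric())
    x1 <- numeric(n_volumes)
    x2 <- numeric(n_volumes)
    for (i in seq_len(nrow(events))) {
      on <- round(events$onset[i] / tr_seconds)          # nearest-sample onset
      ns <- max(1L, round(events$duration[i] / tr_seconds))
      idx <- (on + 1L):min(on + ns, n_volumes)
      if (events$trial_type[i] == "novelty") x1[idx] <- 1 else x2[idx] <- 1
    }
    structure(list(tr_seconds = tr_seconds, n_volumes = n_volumes,
                   x1 = x1, x2 = x2, events = events,
                   scheduled_duration_s = dur, run_index = run),
              class = "task_design")
  })
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf(
    "task design: run %d, %d volumes at TR %.2g s, schedule %.0f s, %d novelty / %d repetition events\n",
    x$run_index, x$n_volumes, x$tr_seconds, x$scheduled_duration_s,
    sum(x$events$trial_type == "novelty"),
    sum(x$events$trial_type == "repetition")))
  invisible(x)
}
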