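# Experimental design: blocked run timelines and probe SF sequences.

FRAME_S <- 0.1 # stimulus frame duration (10 Hz refresh of the probe noise)

# A duration is representable on the timeline iff it is a whole number of
# 0.1 s frames (the finest clock in the experiment).
check_frame_multiple <- function(x, name) {
  if (abs(x / FRAME_S - round(x / FRAME_S)) > 1e-9)
    stopf("%s (%g s) is not a multiple of the %.1f s frame and cannot be sampled on the timeline",
          name, x, FRAME_S)
  invisible(x)
}

#' Build one blocked task run
#'
#' Constructs the per-run timeline: an initial blank, then `n_blocks` task
#' blocks each followed by a blank, sampled at the TR (1 s). The default
#' arguments give the main-task run used throughout: 10 s initial blank and
#' six 40.5 s blocks each followed by a 10 s blank, i.e. 313 TRs. Condition
#' labels are assigned to blocks as a seeded pseudorandom interleave with
#' each condition appearing equally often.
#'
#' @param n_blocks Number of task blocks (default 6).
#' @param block_s Block duration in seconds (default 40.5).
#' @param blank_s Post-block blank duration in seconds (default 10).
#' @param initial_blank_s Blank before the first block (default 10).
#' @param conditions Character vector of condition labels to interleave;
#'   its length must divide `n_blocks`.
#' @param seed Integer seed for the condition interleave.
#' @param tr TR (sampling interval) in seconds; default 1.
#' @return An object of class `psft_run_design`: a list with `tr_seconds`,
#'   `n_trs`, `block_onsets` (s), `block_duration`, `blank_duration`,
#'   `initial_blank`, `condition_per_block`, and `seed`.
#' @examples
#' d <- build_run_design(seed = 1)
#' d$n_trs  # 313
#' @export
build_run_design <- function(n_blocks = 6, block_s = 40.5, blank_s = 10,
                             initial_blank_s = 10,
                             conditions = psft_conditions(), seed = 1L,
                             tr = 1) {
  stopifnot(n_blocks >= 0, block_s > 0, blank_s > 0, initial_blank_s >= 0, tr > 0)
  check_frame_multiple(block_s, "block_s")
  check_frame_multiple(blank_s, "blank_s")
  check_frame_multiple(initial_blank_s, "initial_blank_s")
  check_frame_multiple(tr, "tr")
  if (n_blocks > 0 && length(conditions) > 0 && n_blocks %% length(conditions) != 0)
    stopf("length(conditions) = %d must divide n_blocks = %d",
          length(conditions), n_blocks)

  total_s <- initial_blank_s + n_blocks * (block_s + blank_s)
  n_trs <- as.integer(ceiling(total_s / tr))
  onsets <- if (n_blocks > 0)
    initial_blank_s + (seq_len(n_blocks) - 1) * (block_s + blank_s) else numeric(0)
  cond <- if (n_blocks > 0)
    with_seed(seed, sample(rep(conditions, times = n_blocks / length(conditions))))
  else character(0)

  structure(list(
    tr_seconds = tr, n_trs = n_trs, block_onsets = onsets,
    block_duration = block_s, blank_duration = blank_s,
    initial_blank = initial_blank_s, condition_per_block = cond,
    n_blocks = as.integer(n_blocks), seed = as.integer(seed)
  ), class = "psft_run_design")
}

#' @export
print.psft_run_design <- function(x, ...) {
  cat(sprintf("pSFT run design: %d blocks of %g s (+%g s blank), %d TRs @ %g s\n",
              x$n_blocks, x$block_duration, x$blank_duration, x$n_trs, x$tr_seconds))
  if (x$n_blocks > 0)
    cat("  conditions:", paste(x$condition_per_block, collapse = ", "), "\n")
  invisible(x)
}

#' Build a session of runs
#'
#' Replicates a run design across `n_runs` runs, re-interleaving conditions
#' per run under sub-seeds derived from a single master seed, so any run is
#' regenerable in isolation. With the 9-run default and two blocks per
#' condition per run, each condition appears 18 times per session.
#'
#' @param n_runs Number of runs (default 9).
#' @param design_template A `psft_run_design` giving timing and conditions.
#' @param seed Master integer seed.
#' @return List of `psft_run_design`, one per run; each carries its derived
#'   seed.
#' @export
build_session_schedule <- function(n_runs = 9,
                                   design_template = build_run_design(),
                                   seed = 1L) {
  stopifnot(n_runs >= 1)
  lapply(seq_len(n_runs), function(r) {
    build_run_design(
      n_blocks = design_template$n_blocks,
      block_s = design_template$block_duration,
      blank_s = design_template$blank_duration,
      initial_blank_s = design_template$initial_blank,
      conditions = unique_conditions(design_template),
      seed = derive_seed(seed, r), tr = design_template$tr_seconds
    )
  })
}

unique_conditions <- function(design) {
  # recover the condition label set (balanced design) in a stable order:
  # canonical labels first, anything else alphabetically after
  u <- unique(design$condition_per_block)
  u[order(match(u, psft_conditions(), nomatch = length(u) + 10L), u)]
}

# TR start times (seconds), 0-based.
tr_starts <- function(design) (seq_len(design$n_trs) - 1) * design$tr_seconds

# Index of the block covering each TR start (NA during blanks).
tr_block_index <- function(design) {
  t0 <- tr_starts(design)
  idx <- rep(NA_integer_, design$n_trs)
  for (j in seq_along(design$block_onsets)) {
    on <- design$block_onsets[j]
    idx[t0 >= on - 1e-9 & t0 < on + design$block_duration - 1e-9] <- j
  }
  idx
}

# TRs belonging to block j, optionally including its trailing blank.
block_trs <- function(design, j, include_blank = TRUE) {
  t0 <- tr_starts(design)
  on <- design$block_onsets[j]
  end <- on + design$block_duration + if (include_blank) design$blank_duration else 0
  which(t0 >= on - 1e-9 & t0 < end - 1e-9)
}

#' Build the probe spatial-frequency sequence for a run
#'
#' Within each task block, `n_levels` probe center SFs, logarithmically
#' spaced between `sf_min` and `sf_max`, are presented once each as a
#' seeded pseudorandom permutation at the 10 Hz frame rate. Each level
#' occupies a contiguous dwell of `floor(frames_per_block / n_levels)`
#' frames (1.0 s with the defaults); leftover frames extend the final
#' level. Blank periods carry the sentinel SF `blank_code` (0.0001 cpd)
#' so the log-transform in the tuning model is defined while contributing
#' essentially zero response. A TR-resolution track is derived from the
#' frame track by majority occupancy, ties resolved in favor of the level
#' with the earlier onset within the TR.
#'
#' @param design A `psft_run_design`.
#' @param n_levels Number of probe SF levels (default 40).
#' @param sf_min,sf_max Probe SF range in cpd (defaults 0.1 and 12).
#' @param frame_hz Stimulus refresh rate in Hz (default 10).
#' @param seed Integer seed for the per-block permutations.
#' @param blank_code Sentinel SF for blanks (default 1e-4 cpd).
#' @return An object of class `psft_sf_sequence`: list with `sf_per_tr`,
#'   `sf_per_frame`, `sf_levels`, `blank_code`, `frame_hz`, `n_trs`, `seed`.
#' @examples
#' d <- build_run_design(seed = 1)
#' s <- build_probe_sf_sequence(d, seed = 1)
#' length(unique(s$sf_per_frame)) # 41 = 40 levels + blank sentinel
#' @export
build_probe_sf_sequence <- function(design, n_levels = 40, sf_min = 0.1,
                                    sf_max = 12, frame_hz = 10, seed = 1L,
                                    blank_code = 1e-4) {
  stopifnot(inherits(design, "psft_run_design"), n_levels >= 2,
            sf_min > 0, sf_min < sf_max, frame_hz > 0)
  levels <- exp(seq(log(sf_min), log(sf_max), length.out = n_levels))
  n_frames <- as.integer(round(design$n_trs * design$tr_seconds * frame_hz))
  ft <- (seq_len(n_frames) - 1) / frame_hz # frame start times
  sf_frame <- rep(blank_code, n_frames)

  frames_per_block <- as.integer(round(design$block_duration * frame_hz))
  if (frames_per_block < n_levels)
    stopf("block of %g s (%d frames) too short to present %d SF levels",
          design$block_duration, frames_per_block, n_levels)
  dwell <- frames_per_block %/% n_levels

  for (j in seq_along(design$block_onsets)) {
    on <- design$block_onsets[j]
    fidx <- which(ft >= on - 1e-9 & ft < on + design$block_duration - 1e-9)
    perm <- with_seed(derive_seed(seed, j), sample.int(n_levels))
    lev_per_frame <- rep(perm[n_levels], length(fidx)) # remainder -> final level
    lev_per_frame[seq_len(dwell * n_levels)] <- rep(perm, each = dwell)
    sf_frame[fidx] <- levels[lev_per_frame]
  }

  # TR track: majority occupancy among the TR's frames; ties -> earlier onset
  fpt <- as.integer(round(design$tr_seconds * frame_hz))
  sf_tr <- vapply(seq_len(design$n_trs), function(t) {
    fr <- sf_frame[((t - 1) * fpt + 1):(t * fpt)]
    u <- unique(fr) # order of first occurrence = onset order within the TR
    cnt <- tabulate(match(fr, u))
    u[cnt == max(cnt)][1] # tie -> earlier-onset level
  }, numeric(1))

  structure(list(
    sf_per_tr = sf_tr, sf_per_frame = sf_frame, sf_levels = levels,
    blank_code = blank_code, frame_hz = frame_hz, n_trs = design$n_trs,
    seed = as.integer(seed)
  ), class = "psft_sf_sequence")
}

#' Tabulate a run design and SF sequence per TR
#'
#' @param design A `psft_run_design`.
#' @param sfseq Matching `psft_sf_sequence` (optional).
#' @param run Run index recorded in the table.
#' @return data.frame with one row per TR: `run`, `t` (TR start, s),
#'   `block_index` (NA during blanks), `condition`, and `sf_cpd` when a
#'   sequence is supplied.
#' @export
design_timeline <- function(design, sfseq = NULL, run = 1L) {
  bi <- tr_block_index(design)
  out <- data.frame(
    run = as.integer(run), t = tr_starts(design), block_index = bi,
    condition = ifelse(is.na(bi), NA_character_, design$condition_per_block[bi]),
    stringsAsFactors = FALSE
  )
  if (!is.null(sfseq)) {
    stopifnot(sfseq$n_trs == design$n_trs)
    out$sf_cpd <- sfseq$sf_per_tr
  }
  out
}

#' Write a design (and SF sequence) to TSV with a JSON sidecar
#'
#' @param design A `psft_run_design`.
#' @param sfseq Optional matching `psft_sf_sequence`.
#' @param path Output TSV path; a `.json` sidecar with generation
#'   parameters and seeds is written alongside.
#' @param run Run index recorded in the table.
#' @return Invisibly, the TSV path.
#' @export
write_design <- function(design, sfseq = NULL, path, run = 1L) {
  tl <- design_timeline(design, sfseq, run = run)
  write.table(tl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(
    tr_seconds = design$tr_seconds, n_trs = design$n_trs,
    n_blocks = design$n_blocks, block_duration = design$block_duration,
    blank_duration = design$blank_duration,
    initial_blank = design$initial_blank, design_seed = design$seed
  )
  if (!is.null(sfseq))
    side <- c(side, list(sf_levels = sfseq$sf_levels,
                         blank_code = sfseq$blank_code,
                         frame_hz = sfseq$frame_hz, sequence_seed = sfseq$seed))
  jsonlite::write_json(side, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
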