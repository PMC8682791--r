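# DNA fiber (molecular combing) analysis: classify dual-pulse IdU/CldU
# tracks, keep only progressing forks (CldU directly preceded by a clear IdU
# signal), and convert the second-pulse track length to replication fork
# speed using the combing calibration 1 um = 2 kb.

#' Classify a dual-labelled fiber track
#'
#' A track is `progressing` iff a CldU segment is directly preceded by an IdU
#' segment along the fiber and the IdU signal is "clear" (length >=
#' `min_idu_um`). Tracks with only one label are `cldu_only` / `idu_only`;
#' any other configuration (e.g. reversed order) is `other`. Only
#' progressing tracks enter fork-speed summaries.
#'
#' @param track List or one-row data frame with `order` (character vector or
#'   ">"-separated string of segment labels along the fiber), `idu_len_um`
#'   and `cldu_len_um`.
#' @param min_idu_um Minimum IdU track length accepted as a clear signal.
#' @return One of `"progressing"`, `"cldu_only"`, `"idu_only"`, `"other"`.
#' @export
classify_track <- function(track, min_idu_um = 1) {
  ord <- track$order
  if (is.character(ord) && length(ord) == 1L && grepl(">", ord))
    ord <- strsplit(ord, ">", fixed = TRUE)[[1]]
  ord <- ord[nzchar(ord)]
  if (length(ord) == 0L) stopf("empty track: no labelled segments")
  if (!all(ord %in% c("IdU", "CldU")))
    stopf("unknown segment label(s): %s",
          paste(setdiff(ord, c("IdU", "CldU")), collapse = ", "))
  idu <- track$idu_len_um %||% 0
  cldu <- track$cldu_len_um %||% 0
  follows <- any(ord[-length(ord)] == "IdU" & ord[-1] == "CldU")
  if (follows && idu >= min_idu_um && cldu > 0) return("progressing")
  if (all(ord == "CldU")) return("cldu_only")
  if (all(ord == "IdU")) return("idu_only")
  "other"
}

#' Replication fork speed from a progressing track
#'
#' `speed = cldu_len_um * conversion_kb_per_um / pulse_min`: only the second
#' (CldU) pulse length is used, converted with the combing calibration
#' (default 2 kb per um) and divided by the labelling time (default 15 min).
#'
#' @param track A track (see [classify_track()]); must be progressing.
#' @param pulse_min CldU pulse duration in minutes.
#' @param conversion_kb_per_um Length calibration, kb per micrometre.
#' @param min_idu_um Passed to [classify_track()].
#' @return One-row data frame: `speed_kb_per_min`, `pulse_min`,
#'   `conversion_kb_per_um`.
#' @export
fork_speed <- function(track, pulse_min = 15, conversion_kb_per_um = 2,
                       min_idu_um = 1) {
  assert_scalar_num(pulse_min, "pulse_min", lower = 0, strict = TRUE)
  pat <- classify_track(track, min_idu_um)
  if (pat != "progressing")
    stopf("fork speed is defined only for progressing tracks (got %s)", pat)
  data.frame(speed_kb_per_min = track$cldu_len_um * conversion_kb_per_um / pulse_min,
             pulse_min = pulse_min,
             conversion_kb_per_um = conversion_kb_per_um)
}

#' Fork speeds for a whole track table
#'
#' Classifies every track and computes speeds for the progressing ones.
#'
#' @param tracks Data frame with `track_id`, `order`, `idu_len_um`,
#'   `cldu_len_um` (and optionally `ssdna_ok`, FALSE rows are dropped).
#' @param pulse_min,conversion_kb_per_um,min_idu_um See [fork_speed()].
#' @return Data frame: `track_id`, `pattern`, `speed_kb_per_min` (NA for
#'   non-progressing tracks).
#' @export
fiber_speeds <- function(tracks, pulse_min = 15, conversion_kb_per_um = 2,
                         min_idu_um = 1) {
  if ("ssdna_ok" %in% names(tracks)) tracks <- tracks[tracks$ssdna_ok, ]
  pat <- vapply(seq_len(nrow(tracks)), function(i)
    classify_track(tracks[i, ], min_idu_um), "")
  speed <- ifelse(pat == "progressing",
                  tracks$cldu_len_um * conversion_kb_per_um / pulse_min, NA_real_)
  data.frame(track_id = tracks$track_id, pattern = pat,
             speed_kb_per_min = speed, stringsAsFactors = FALSE)
}

#' Summarize replication fork speed per genotype
#'
#' Per-group median and quartiles (for violin/box reporting) and pairwise
#' Mann-Whitney-Wilcoxon tests (delegating to [compare_groups()]).
#'
#' @param results_by_group Named list mapping group to a numeric vector of
#'   fork speeds (>= 2 per group) or a data frame with `speed_kb_per_min`.
#' @return List with `summary` (group, n, median, q25, q75) and `tests`
#'   (group_a, group_b, delta_median, p_value).
#' @export
summarize_rfs <- function(results_by_group) {
  vals <- lapply(results_by_group, function(x) {
    v <- if (is.data.frame(x)) x$speed_kb_per_min else as.numeric(x)
    v[!is.na(v)]
  })
  if (any(vapply(vals, length, 1L) < 2L))
    stopf("each group needs >= 2 fork-speed results")
  groups <- names(vals)
  summ <- do.call(rbind, lapply(groups, function(gn) {
    s <- summarize_distribution(vals[[gn]])
    data.frame(group = gn, n = s$n, median = s$median, q25 = s$q25,
               q75 = s$q75, stringsAsFactors = FALSE)
  }))
  tests <- if (length(groups) >= 2L) {
    prs <- utils::combn(groups, 2, simplify = FALSE)
    do.call(rbind, lapply(prs, function(pr) {
      a <- vals[[pr[1]]]; b <- vals[[pr[2]]]
      data.frame(group_a = pr[1], group_b = pr[2],
                 delta_median = stats::median(a) - stats::median(b),
                 p_value = compare_groups(a, b, test = "mann_whitney")$p_value,
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  list(summary = summ, tests = tests)
}
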