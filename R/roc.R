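# ROC threshold calibration: label scanned windows against known sites,
# sweep thresholds, summarize with AUROC, choose an operating point.

#' Label scanned windows as known-site positives or background negatives
#'
#' In `"coordinates"` mode a window is positive when its (contig, start)
#' — and strand, if the known table has one — matches a known site.
#' Known sites with no matching window are reported with a warning and
#' excluded.  In `"sequences"` mode every window whose (strand-oriented)
#' sequence equals one of the known site sequences is positive, which
#' requires the scanned `genome`.  By default, windows that are not
#' positive but overlap a positive window by at least half the motif
#' width are excluded from the negatives (`strict = TRUE` keeps every
#' non-identical window as a negative).
#'
#' @param windows A `scan_result`.
#' @param known Known sites: tibble with `contig` and `start` (optionally
#'   `strand`) in coordinate mode, or a character vector / `site` column
#'   of k-mer sequences in sequence mode.
#' @param mode `"coordinates"` or `"sequences"`.
#' @param genome Genome tibble; required for sequence mode.
#' @param strict Keep near-overlapping windows among the negatives.
#' @return The window tibble with a `label` column (`"positive"` /
#'   `"negative"`), overlap-excluded rows dropped; class
#'   `labeled_windows`.
#' @export
label_windows <- function(windows, known, mode = c("coordinates", "sequences"),
                          genome = NULL, strict = FALSE) {
  mode <- match.arg(mode)
  k <- attr(windows, "k")
  win <- as_tibble(windows)
  if (nrow(win) == 0L) stop_invalid("No scanned windows to label.")
  if (is.null(k)) k <- win$end[1] - win$start[1] + 1L

  if (mode == "coordinates") {
    if (is.data.frame(known)) known_tb <- known
    else stop_invalid("Coordinate mode needs a data frame of known-site coordinates.")
    if (nrow(known_tb) == 0L) stop_invalid("The known-site set is empty: ROC is undefined.")
    if (!all(c("contig", "start") %in% names(known_tb))) {
      stop_invalid("Known-site table must have `contig` and `start` columns.")
    }
    use_strand <- "strand" %in% names(known_tb)
    key <- function(tb) {
      if (use_strand) paste(tb$contig, tb$start, tb$strand)
      else paste(tb$contig, tb$start)
    }
    pos <- key(win) %in% key(known_tb)
    found <- key(known_tb) %in% key(win)
    if (!all(found)) {
      warn(sprintf("%d known site(s) not found among scanned windows; excluded from positives (first: %s).",
                   sum(!found), key(known_tb)[!found][1]))
    }
  } else {
    if (is.data.frame(known)) known <- known$site
    known <- toupper(known)
    if (length(known) == 0L) stop_invalid("The known-site set is empty: ROC is undefined.")
    if (is.null(genome)) stop_invalid("Sequence mode needs the scanned `genome` to extract window sequences.")
    pos <- window_sequences(win, genome) %in% known
  }
  if (!any(pos)) stop_invalid("No positive windows: ROC is undefined.")

  keep <- rep(TRUE, nrow(win))
  if (!strict) {
    # drop non-positive windows overlapping a positive by >= k/2 bp,
    # i.e. start within floor(k/2) of a positive start on the same contig
    slack <- k %/% 2L
    pw <- win[pos, c("contig", "start")]
    for (ct in unique(pw$contig)) {
      on_ct <- win$contig == ct & !pos
      if (!any(on_ct)) next
      d <- vapply(win$start[on_ct],
                  function(s) min(abs(s - pw$start[pw$contig == ct])),
                  numeric(1))
      keep[on_ct][d <= slack] <- FALSE
    }
  }
  out <- win[keep, ]
  out$label <- ifelse(pos[keep], "positive", "negative")
  if (!any(out$label == "negative")) stop_invalid("No negative windows: ROC is undefined.")
  structure(out, k = k, class = c("labeled_windows", class(tibble())))
}

#' ROC curve over a threshold sweep
#'
#' `TPR(t)` is the fraction of positive windows scoring at least `t`;
#' `FPR(t)` the same fraction of negatives.  Both are non-increasing in
#' the threshold; sweeping from below the minimum to above the maximum
#' score traverses (1,1) to (0,0).
#'
#' @param labeled A `labeled_windows` tibble.
#' @param thresholds Score thresholds in bits, sorted ascending.  The
#'   default integer sweep 9..19 matches the usual calibration grid for
#'   14-bp cre-like matrices; see [threshold_grid()] for `"lo:hi:step"`
#'   syntax.
#' @return Tibble of class `roc_curve` with `threshold`, `tp`, `fp`,
#'   `tpr`, `fpr`; the rank-based AUROC and class counts are attached as
#'   attributes (see [glance()]).
#' @export
roc_curve <- function(labeled, thresholds = 9:19) {
  if (!"label" %in% names(labeled)) stop_invalid("`labeled` must come from label_windows().")
  thresholds <- sort(as.numeric(thresholds))
  pos <- labeled$score[labeled$label == "positive"]
  neg <- labeled$score[labeled$label == "negative"]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop_invalid("ROC needs at least one positive and one negative window.")
  }
  tp <- vapply(thresholds, function(t) sum(pos >= t), numeric(1))
  fp <- vapply(thresholds, function(t) sum(neg >= t), numeric(1))
  curve <- tibble(threshold = thresholds, tp = as.integer(tp), fp = as.integer(fp),
                  tpr = tp / length(pos), fpr = fp / length(neg))
  structure(curve, auroc = auroc(labeled), n_pos = length(pos), n_neg = length(neg),
            class = c("roc_curve", class(tibble())))
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney estimator: the probability that a random positive
#' outscores a random negative, ties counted half, computed from midranks.
#'
#' @param labeled A `labeled_windows` tibble, or a numeric score vector
#'   (then `labels` is required).
#' @param labels Logical or `"positive"`/`"negative"` vector parallel to
#'   the scores.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labeled, labels = NULL) {
  if (is.data.frame(labeled)) {
    scores <- labeled$score
    is_pos <- labeled$label == "positive"
  } else {
    scores <- labeled
    is_pos <- if (is.logical(labels)) labels else labels == "positive"
  }
  np <- sum(is_pos)
  nn <- sum(!is_pos)
  if (np == 0L || nn == 0L) stop_invalid("AUROC needs both positives and negatives.")
  r <- rank(scores, ties.method = "average")
  (sum(r[is_pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Choose an operating threshold from a ROC curve
#'
#' @param curve A `roc_curve`.
#' @param criterion `"youden"` maximizes Youden's J = TPR - FPR (ties go
#'   to the higher, more specific threshold); `"fpr_ceiling"` takes the
#'   maximum TPR among thresholds with FPR at most `value` (then the
#'   highest such threshold); `"fixed"` returns the grid row at
#'   `value`.
#' @param value FPR ceiling or fixed threshold, depending on `criterion`.
#' @return One-row tibble: `threshold`, `tpr`, `fpr`, `criterion`.
#' @export
choose_threshold <- function(curve, criterion = c("youden", "fpr_ceiling", "fixed"),
                             value = NULL) {
  criterion <- match.arg(criterion)
  if (nrow(curve) == 0L) stop_invalid("Empty ROC curve.")
  row <- switch(criterion,
    youden = {
      j <- curve$tpr - curve$fpr
      best <- which(j == max(j))
      curve[best[length(best)], ]  # curve sorted ascending: last = highest threshold
    },
    fpr_ceiling = {
      if (is.null(value)) stop_invalid("`value` (the FPR ceiling) is required.")
      ok <- curve$fpr <= value
      if (!any(ok)) stop_invalid(sprintf("No threshold achieves FPR <= %g.", value))
      cand <- curve[ok, ]
      best <- which(cand$tpr == max(cand$tpr))
      cand[best[length(best)], ]
    },
    fixed = {
      if (is.null(value)) stop_invalid("`value` (the fixed threshold) is required.")
      i <- which(abs(curve$threshold - value) < 1e-9)
      if (length(i) == 0L) {
        stop_invalid(sprintf("Threshold %g is not on the curve's grid; add it to `thresholds`.", value))
      }
      curve[i[1], ]
    })
  tibble(threshold = row$threshold, tpr = row$tpr, fpr = row$fpr, criterion = criterion)
}

#' Parse a "lo:hi:step" threshold grid
#'
#' @param spec Grid string, e.g. `"9:19:1"` (the default calibration
#'   sweep) or `"8:16:0.25"`.
#' @return Numeric vector of thresholds.
#' @export
threshold_grid <- function(spec = "9:19:1") {
  parts <- suppressWarnings(as.numeric(strsplit(spec, ":", fixed = TRUE)[[1]]))
  if (length(parts) != 3L || anyNA(parts) || parts[3] <= 0) {
    stop_invalid(sprintf("Threshold grid must be \"lo:hi:step\", got \"%s\".", spec))
  }
  seq(parts[1], parts[2], by = parts[3])
}
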