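#' Estimate insert-size statistics from within-contig pairs
#'
#' Sample mean and sd of the outer distances of proper (forward-reverse,
#' same-contig) pairs, after discarding distances greater than 10 times the
#' median.
#'
#' @param distances numeric vector of outer distances of proper within-contig
#'   pairs.
#' @return list of class `insert_stats` with `mean`, `sd`, `n`.
#' @export
estimate_insert_stats <- function(distances) {
  distances <- distances[is.finite(distances)]
  med <- stats::median(distances)
  distances <- distances[distances <= 10 * med]
  if (length(distances) < 100) {
    stop("too few proper pairs for insert estimation (", length(distances),
         " < 100)")
  }
  structure(list(mean = mean(distances), sd = stats::sd(distances),
                 n = length(distances)),
            class = "insert_stats")
}

#' Physical fragment coverage of a contig
#'
#' Counts, per base, the number of fragments containing that base, by a
#' difference array (O(n + m)). Fragments are clipped to contig bounds.
#'
#' @param contig_len contig length in bp.
#' @param starts,ends fragment intervals, 0-based half-open.
#' @return integer vector of per-base fragment coverage.
#' @export
physical_coverage <- function(contig_len, starts, ends) {
  cpp_phys_cov(as.integer(contig_len), as.integer(starts), as.integer(ends))
}

#' Detect low-quality intervals (LQIs)
#'
#' Maximal runs of physical coverage below `min_depth` become LQIs,
#' classified by position: touching base 0 (`start`), touching the contig
#' end (`end`), spanning the whole contig (`whole`), otherwise `internal`.
#' Contig termini cannot accrue full physical coverage (pairs cannot span
#' past an end), so terminal runs no longer than `end_exempt_bp` are
#' tolerated unless their coverage is zero throughout and they exceed
#' `end_exempt_bp`.
#'
#' @param coverage per-base integer coverage from [physical_coverage].
#' @param min_depth minimum acceptable fragment depth (default 7).
#' @param end_exempt_bp tolerance for terminal low-coverage runs (typically
#'   the insert mean; 0 disables the exemption).
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `kind`.
#' @export
detect_lqi <- function(coverage, min_depth = 7L, end_exempt_bp = 0L) {
  n <- length(coverage)
  low <- coverage < min_depth
  if (!any(low)) {
    return(data.frame(start = integer(), end = integer(), kind = character()))
  }
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  kind <- ifelse(runs$start == 0 & runs$end == n, "whole",
          ifelse(runs$start == 0, "start",
          ifelse(runs$end == n, "end", "internal")))
  runs$kind <- kind
  if (end_exempt_bp > 0) {
    len <- runs$end - runs$start
    exempt <- runs$kind %in% c("start", "end") & len <= end_exempt_bp
    runs <- runs[!exempt, , drop = FALSE]
  }
  rownames(runs) <- NULL
  runs
}

#' Trim and split contigs at low-quality intervals
#'
#' Internal LQIs split a contig into left/right parts (the LQI bases are
#' dropped); start/end LQIs trim; a whole-contig LQI drops the contig. Parts
#' shorter than `min_part` are dropped. New ids are `parent.1`, `parent.2`,
#' ... for split/trimmed contigs; untouched contigs keep their id.
#'
#' @param contigs a [seq_set].
#' @param lqis named list (by contig id) of [detect_lqi] data.frames.
#' @param min_part minimum length of an emitted part (default 42, twice the
#'   alignment k-mer).
#' @return list with `contigs` (corrected [seq_set]) and `report`
#'   (data.frame contig, start, end, kind, action).
#' @export
correct_contigs <- function(contigs, lqis, min_part = 42L) {
  out_id <- character(0); out_seq <- character(0)
  rep_rows <- list()
  for (i in seq_along(contigs$id)) {
    id <- contigs$id[i]
    s <- contigs$seq[i]
    n <- nchar(s)
    lq <- lqis[[id]]
    if (is.null(lq) || nrow(lq) == 0) {
      out_id <- c(out_id, id); out_seq <- c(out_seq, s)
      next
    }
    if (any(lq$kind == "whole")) {
      rep_rows[[length(rep_rows) + 1]] <-
        data.frame(contig = id, start = 0L, end = n, kind = "whole",
                   action = "drop")
      next
    }
    lq <- lq[order(lq$start), , drop = FALSE]
    # keep intervals = complement of the LQIs
    keep_start <- c(0L, lq$end)
    keep_end <- c(lq$start, n)
    ok <- keep_end - keep_start >= min_part
    parts <- substring(s, keep_start[ok] + 1L, keep_end[ok])
    ids <- if (length(parts) == 1 && nrow(lq) == 0) id else
      paste0(id, ".", seq_along(parts))
    if (length(parts)) {
      out_id <- c(out_id, ids); out_seq <- c(out_seq, parts)
    }
    act <- ifelse(lq$kind == "internal", "split", "trim")
    rep_rows[[length(rep_rows) + 1]] <-
      data.frame(contig = id, start = lq$start, end = lq$end, kind = lq$kind,
                 action = act)
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(contig = character(), start = integer(), end = integer(),
               kind = character(), action = character())
  list(contigs = seq_set(out_id, out_seq), report = report)
}

#' Chimera detection and correction from short-read pairs
#'
#' Maps paired short reads to the contigs (shortr preset), estimates the
#' insert-size distribution, converts pairs mapped at the expected
#' orientation and distance (within mean +/- 2.5 sd) into physical
#' fragments, and trims/splits contigs at low-quality intervals of the
#' fragment coverage.
#'
#' @param contigs a [seq_set] of draft contigs.
#' @param mate1,mate2 paired short reads ([seq_set]s, forward-reverse).
#' @param min_depth LQI depth threshold (default 7).
#' @param scale_min_depth if TRUE, use `max(2, round(7 * coverage / 50))`
#'   for low-coverage runs (default off).
#' @param min_frag_cov pairs become physical fragments only when both mates
#'   aligned near full length (covered fraction at least this); partially
#'   covered (clipped) mates are the signature of a junction and must not
#'   blanket it.
#' @return list with `contigs` (corrected), `report`, `insert_stats`, and
#'   `coverage` (per-contig mean short-read base coverage).
#' @export
run_contig_qc <- function(contigs, mate1, mate2, min_depth = 7L,
                          scale_min_depth = FALSE, min_frag_cov = 0.85) {
  ps <- preset("shortr")
  idx <- build_index(contigs, ps)
  mp <- map_pair(mate1, mate2, idx, ps)
  a1 <- mp$aln1; a2 <- mp$aln2
  acc <- mp$accept
  same <- acc & a1$target == a2$target
  # proper forward-reverse orientation: opposite strands
  fr <- same & !is.na(a1$strand) & a1$strand != a2$strand
  rl1 <- nchar(mate1$seq); rl2 <- nchar(mate2$seq)
  left <- pmin(a1$pos, a2$pos)
  right <- pmax(a1$pos + rl1, a2$pos + rl2)
  dist <- right - left
  ist <- estimate_insert_stats(dist[fr])
  lo <- ist$mean - 2.5 * ist$sd
  hi <- ist$mean + 2.5 * ist$sd
  frag <- fr & dist >= lo & dist <= hi &
    a1$covered >= min_frag_cov & a2$covered >= min_frag_cov
  read_len <- max(rl1)
  clen <- seq_lengths(contigs)
  names(clen) <- contigs$id
  # per-contig base coverage from mapped mates
  basecov <- tapply(c(rl1[acc], rl2[acc]),
                    c(a1$target[acc], a2$target[acc]), sum)
  covmean <- stats::setNames(rep(0, length(contigs$id)), contigs$id)
  covmean[names(basecov)] <- basecov / clen[names(basecov)]
  if (scale_min_depth) {
    pair_cov <- sum(as.numeric(rl1) + rl2) / sum(as.numeric(clen))
    min_depth <- max(2L, round(7 * pair_cov / 50))
  }
  lqis <- list()
  for (i in seq_along(contigs$id)) {
    id <- contigs$id[i]
    sel <- frag & a1$target == id
    sel[is.na(sel)] <- FALSE
    cov <- physical_coverage(clen[i], left[sel], right[sel])
    lqis[[id]] <- detect_lqi(cov, min_depth,
                             end_exempt_bp = ceiling(ist$mean))
  }
  cc <- correct_contigs(contigs, lqis)
  list(contigs = cc$contigs, report = cc$report, insert_stats = ist,
       coverage = covmean)
}
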