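# Distance-conservation scoring: per-pair statistics across an ensemble,
# the inverse-coefficient-of-variation score, and the ranked table.

#' Euclidean C-alpha distance of one pair in one bundle
#'
#' @param bundle an [aligned_bundle()].
#' @param a,b BW ids (or `"h.ii"` strings) of the two positions.
#' @return distance in Angstrom.
#' @export
pair_distance <- function(bundle, a, b) {
  stopifnot(inherits(bundle, "aligned_bundle"))
  if (is.character(a)) a <- bw_parse(a)
  if (is.character(b)) b <- bw_parse(b)
  ia <- match(as.integer(a), bundle$present)
  ib <- match(as.integer(b), bundle$present)
  if (anyNA(ia) || anyNA(ib)) {
    stop("position missing from bundle: ",
         paste(bw_chr(c(a[is.na(ia)], b[is.na(ib)])), collapse = ", "))
  }
  unname(sqrt(rowSums((bundle$ca[ia, , drop = FALSE] -
                         bundle$ca[ib, , drop = FALSE])^2)))
}

#' Per-pair distance statistics over an ensemble
#'
#' For every unordered pair of positions common to all members, computes the
#' mean, standard deviation, minimum and maximum of the C-alpha distance over
#' the members, and the conservation score: the inverse coefficient of
#' variation, `mean / sd`. Higher scores mean more conserved spacing. The
#' standard deviation is the population form (divide by n). Pairs with zero
#' spread get their score capped at `score_cap` and flagged.
#'
#' @param ensemble a [build_set()] ensemble.
#' @param defn the governing [bundle_definition()].
#' @param sd_convention `"population"` (default) or `"sample"`.
#' @param score_cap finite sentinel replacing an infinite score when sd = 0.
#' @return data.frame with one row per scoreable pair: `a`, `b`, `bw_a`,
#'   `bw_b`, `helix_pair`, `section_pair`, `adjacent`, `mean`, `sd`, `min`,
#'   `max`, `score`, `capped`, `n_members`.
#' @export
score_set <- function(ensemble, defn = default_bundle(),
                      sd_convention = c("population", "sample"),
                      score_cap = 1e6) {
  stopifnot(inherits(ensemble, "bundle_ensemble"))
  sd_convention <- match.arg(sd_convention)
  pr <- pair_table(defn, ensemble$common)
  ia <- match(pr$a, ensemble$common)
  ib <- match(pr$b, ensemble$common)
  nm <- length(ensemble$members)
  D <- matrix(0, nrow(pr), nm)
  for (k in seq_len(nm)) {
    ca <- ensemble$members[[k]]$ca
    idx <- match(ensemble$common, ensemble$members[[k]]$present)
    ca <- ca[idx, , drop = FALSE]
    D[, k] <- sqrt((ca[ia, 1] - ca[ib, 1])^2 +
                   (ca[ia, 2] - ca[ib, 2])^2 +
                   (ca[ia, 3] - ca[ib, 3])^2)
  }
  m <- rowMeans(D)
  ss <- rowSums((D - m)^2)
  v <- if (sd_convention == "population") ss / nm else ss / (nm - 1L)
  s <- sqrt(pmax(v, 0))
  capped <- s <= 0
  score <- ifelse(capped, score_cap, m / s)
  out <- pr[, c("a", "b", "bw_a", "bw_b", "helix_pair", "section_pair",
                "adjacent")]
  out$mean <- m
  out$sd <- s
  out$min <- do.call(pmin, as.data.frame(D))
  out$max <- do.call(pmax, as.data.frame(D))
  out$score <- score
  out$capped <- capped
  out$n_members <- nm
  out
}

#' Rank pairs by conservation score
#'
#' Sorts descending by score with deterministic tie-breaking by canonical
#' pair order. Adjacent pairs (consecutive BW indices within a helix) are
#' excluded before ranks are assigned when `exclude_adjacent` is `TRUE`,
#' since their ~3.8 A spacing is trivially invariant.
#'
#' @param stats pair statistics from [score_set()].
#' @param exclude_adjacent drop adjacent pairs before ranking (default TRUE).
#' @param top_n how many top rows to keep in the `top` table (default 1000).
#' @return list with `ranked` (all retained rows, ranked) and `top` (the
#'   first `top_n` rows). If `top_n` exceeds the available rows, all rows are
#'   returned with a warning.
#' @export
rank_pairs <- function(stats, exclude_adjacent = TRUE, top_n = 1000L) {
  stopifnot(is.data.frame(stats), nrow(stats) > 0)
  r <- if (exclude_adjacent) stats[!stats$adjacent, , drop = FALSE] else stats
  if (nrow(r) == 0L) stop("no pairs left to rank")
  r <- r[order(-r$score, r$a, r$b), , drop = FALSE]
  r$rank <- seq_len(nrow(r))
  rownames(r) <- NULL
  if (top_n > nrow(r)) {
    warning("top_n = ", top_n, " exceeds the ", nrow(r),
            " available pairs; returning all")
    top_n <- nrow(r)
  }
  list(ranked = r, top = r[seq_len(top_n), , drop = FALSE])
}

#' Fit a distance-conservation analysis to a 7TM ensemble
#'
#' The central analysis: every C-alpha/C-alpha distance over the positions
#' common to all members of the ensemble is scored by the inverse coefficient
#' of variation (mean distance over the members divided by its standard
#' deviation), adjacent backbone pairs are set aside, and the remaining pairs
#' are ranked so the most-conserved `top_n` population can be decomposed by
#' helix pair and helix-section pair (see [summary.dcons()],
#' [summarize_helix_pairs()], [summarize_section_pairs()]).
#'
#' @param ensemble a [build_set()] ensemble (>= 2 members).
#' @param defn the governing [bundle_definition()].
#' @param top_n size of the top-ranked population analysed downstream
#'   (default 1000).
#' @param exclude_adjacent omit adjacent pairs from the ranking (default
#'   TRUE).
#' @inheritParams score_set
#' @return An object of class `dcons`: list with `stats` (all scoreable
#'   pairs), `ranked`, `top`, `universe` (scoreable pair count), `n_members`,
#'   `top_n`, `exclude_adjacent`, `set_name`, `defn` and the matched call.
#' @examples
#' defn <- default_bundle()
#' ens <- generate_ensemble(preset("rhodopsin_like", n_members = 6, seed = 1))
#' fit <- dcons(ens, defn, top_n = 200)
#' fit
#' head(summary(fit)$helix_pairs)
#' @export
dcons <- function(ensemble, defn = default_bundle(), top_n = 1000L,
                  exclude_adjacent = TRUE,
                  sd_convention = c("population", "sample"),
                  score_cap = 1e6) {
  sd_convention <- match.arg(sd_convention)
  stats <- score_set(ensemble, defn, sd_convention, score_cap)
  rk <- rank_pairs(stats, exclude_adjacent, top_n)
  structure(list(stats = stats, ranked = rk$ranked, top = rk$top,
                 universe = nrow(stats), n_members = length(ensemble$members),
                 common = ensemble$common,
                 top_n = nrow(rk$top), exclude_adjacent = exclude_adjacent,
                 sd_convention = sd_convention, score_cap = score_cap,
                 set_name = ensemble$name, defn = defn,
                 call = match.call()),
            class = "dcons")
}

#' @export
print.dcons <- function(x, ...) {
  cat(sprintf("C-alpha distance conservation: set '%s', %d members\n",
              x$set_name, x$n_members))
  cat(sprintf("  scoreable pairs: %d (%d positions%s)\n", x$universe,
              length(x$common),
              if (x$exclude_adjacent)
                sprintf("; %d adjacent pairs excluded from ranking",
                        sum(x$stats$adjacent)) else ""))
  sc <- x$ranked$score
  cat(sprintf("  score range (ranked): %.2f - %.2f; mean %.1f\n",
              min(sc), max(sc), mean(sc)))
  cat(sprintf("  top %d threshold score: %.2f (%.1f%% of scoreable pairs)\n",
              x$top_n, min(x$top$score), 100 * x$top_n / x$universe))
  invisible(x)
}

#' Summarise a distance-conservation fit
#'
#' @param object a [dcons()] fit.
#' @param denominator see [summarize_helix_pairs()].
#' @param ... ignored.
#' @return An object of class `summary.dcons` carrying the helix-pair
#'   summary, the leading intrahelical and interhelical bins, and headline
#'   score statistics.
#' @export
summary.dcons <- function(object, denominator = c("all", "nonadjacent"), ...) {
  denominator <- match.arg(denominator)
  hp <- summarize_helix_pairs(object, denominator = denominator)
  intra <- hp[substr(hp$label, 1, 99) %in%
                paste0(.ROMAN, "-", .ROMAN), , drop = FALSE]
  inter <- hp[!hp$label %in% paste0(.ROMAN, "-", .ROMAN), , drop = FALSE]
  structure(list(set_name = object$set_name, n_members = object$n_members,
                 universe = object$universe, top_n = object$top_n,
                 helix_pairs = hp,
                 top_intra = intra[order(-intra$ratio), , drop = FALSE],
                 top_inter = inter[order(-inter$ratio), , drop = FALSE],
                 mean_score = mean(object$stats$score[!object$stats$capped]),
                 threshold = min(object$top$score)),
            class = "summary.dcons")
}

#' @export
print.summary.dcons <- function(x, ...) {
  cat(sprintf("Distance conservation summary: set '%s' (%d members, %d pairs)\n",
              x$set_name, x$n_members, x$universe))
  cat(sprintf("  mean score %.1f; top-%d threshold %.1f\n",
              x$mean_score, x$top_n, x$threshold))
  cat("  leading intrahelical bins (by top-N ratio):\n")
  print(utils::head(x$top_intra, 3), row.names = FALSE)
  cat("  leading interhelical bins (by top-N ratio):\n")
  print(utils::head(x$top_inter, 3), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.dcons <- function(x, ...) x$ranked

#' Score and distance histograms of a fit
#'
#' Binned score counts (with and without adjacent pairs), the matching
#' cumulative counts, mean-distance histograms for all pairs and for the
#' top-ranked population, and the (mean, score) scatter rows for export.
#'
#' @param stats a [dcons()] fit or a [score_set()] data.frame.
#' @param score_bin score bin width (default 5).
#' @param dist_bin distance bin width in Angstrom (default 0.5).
#' @param top optional top table (taken from the fit when `stats` is one).
#' @return list of data.frames: `score_hist` (`bin_lo`, `bin_hi`, `count_all`,
#'   `count_nonadjacent`, `cum_all`, `cum_nonadjacent`), `distance_hist`
#'   (`bin_lo`, `bin_hi`, `count_all`, `count_top`), `scatter`
#'   (`mean`, `score`, `adjacent`).
#' @export
score_distance_profile <- function(stats, score_bin = 5, dist_bin = 0.5,
                                   top = NULL) {
  if (inherits(stats, "dcons")) {
    top <- stats$top
    stats <- stats$stats
  }
  stopifnot(is.data.frame(stats), nrow(stats) > 0)
  sc <- stats$score
  lo <- floor(min(sc) / score_bin) * score_bin
  hi <- ceiling(max(sc) / score_bin) * score_bin
  if (hi <= lo) hi <- lo + score_bin
  br <- seq(lo, hi, by = score_bin)
  bin <- cut(sc, br, include.lowest = TRUE, right = FALSE,
             labels = FALSE)
  bin[sc >= hi] <- length(br) - 1L
  count_all <- tabulate(bin, length(br) - 1L)
  count_na <- tabulate(bin[!stats$adjacent], length(br) - 1L)
  score_hist <- data.frame(bin_lo = br[-length(br)], bin_hi = br[-1],
                           count_all = count_all,
                           count_nonadjacent = count_na,
                           cum_all = cumsum(count_all),
                           cum_nonadjacent = cumsum(count_na))
  dmu <- stats$mean
  dlo <- floor(min(dmu) / dist_bin) * dist_bin
  dhi <- ceiling(max(dmu) / dist_bin) * dist_bin
  if (dhi <= dlo) dhi <- dlo + dist_bin
  dbr <- seq(dlo, dhi, by = dist_bin)
  dcut <- function(v) {
    b <- cut(v, dbr, include.lowest = TRUE, right = FALSE, labels = FALSE)
    b[v >= dhi] <- length(dbr) - 1L
    tabulate(b, length(dbr) - 1L)
  }
  distance_hist <- data.frame(bin_lo = dbr[-length(dbr)], bin_hi = dbr[-1],
                              count_all = dcut(dmu),
                              count_top = if (is.null(top)) NA_integer_
                                          else dcut(top$mean))
  list(score_hist = score_hist, distance_hist = distance_hist,
       scatter = data.frame(mean = stats$mean, score = stats$score,
                            adjacent = stats$adjacent))
}

#' Plot a distance-conservation fit
#'
#' @param x a [dcons()] fit.
#' @param type `"score"` (score histogram), `"cumulative"` (cumulative score
#'   counts), `"distance"` (mean-distance histogram, all vs top), or
#'   `"scatter"` (score vs mean distance).
#' @param ... passed to the underlying base-graphics call.
#' @return invisibly, the profile tables used.
#' @export
plot.dcons <- function(x, type = c("score", "cumulative", "distance",
                                   "scatter"), ...) {
  type <- match.arg(type)
  pf <- score_distance_profile(x)
  if (type == "score") {
    mid <- (pf$score_hist$bin_lo + pf$score_hist$bin_hi) / 2
    graphics::barplot(rbind(pf$score_hist$count_all,
                            pf$score_hist$count_nonadjacent),
                      beside = TRUE, names.arg = round(mid),
                      xlab = "score", ylab = "pair count",
                      legend.text = c("all", "non-adjacent"), ...)
  } else if (type == "cumulative") {
    graphics::plot(pf$score_hist$bin_hi, pf$score_hist$cum_all, type = "s",
                   xlab = "score", ylab = "cumulative count", ...)
    graphics::lines(pf$score_hist$bin_hi, pf$score_hist$cum_nonadjacent,
                    type = "s", lty = 2)
  } else if (type == "distance") {
    mid <- (pf$distance_hist$bin_lo + pf$distance_hist$bin_hi) / 2
    graphics::plot(mid, pf$distance_hist$count_all, type = "h",
                   xlab = "mean distance (A)", ylab = "pair count", ...)
    if (!anyNA(pf$distance_hist$count_top)) {
      graphics::points(mid, pf$distance_hist$count_top, col = 2, type = "h")
    }
  } else {
    graphics::plot(pf$scatter$mean, pf$scatter$score,
                   pch = ifelse(pf$scatter$adjacent, 4, 1),
                   cex = 0.4, xlab = "mean distance (A)", ylab = "score", ...)
  }
  invisible(pf)
}
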