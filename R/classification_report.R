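# Decomposition of the top-ranked population into 28 helix-pair and
# 630 section-pair bins, normalised by the possible-pair totals.

# shared binning engine: counts of top rows and of all scoreable rows per label
.bin_counts <- function(fit, by = c("helix_pair", "section_pair"),
                        denominator = c("all", "nonadjacent")) {
  stopifnot(inherits(fit, "dcons"))
  by <- match.arg(by)
  denominator <- match.arg(denominator)
  labs <- pair_labels(fit$defn)
  levels <- if (by == "helix_pair") labs$helix_pairs else labs$section_pairs
  all_rows <- fit$stats
  if (denominator == "nonadjacent") {
    all_rows <- all_rows[!all_rows$adjacent, , drop = FALSE]
  }
  count_all <- table(factor(all_rows[[by]], levels = levels))
  count_top <- table(factor(fit$top[[by]], levels = levels))
  data.frame(label = levels,
             count_top = as.integer(count_top),
             count_all = as.integer(count_all),
             ratio = ifelse(count_all > 0,
                            as.integer(count_top) / as.integer(count_all),
                            NA_real_),
             stringsAsFactors = FALSE)
}

#' Helix-pair decomposition of the top-ranked population
#'
#' Bins the top-N pairs of a fit into the 28 unordered helix pairs
#' (7 intrahelical + 21 interhelical) and normalises each count by the total
#' number of scoreable pairs in that bin, so helices of different lengths are
#' comparable. With the default `denominator = "all"` the totals count every
#' combinatorial pair over the common positions, including the adjacent pairs
#' that the ranking itself set aside; `"nonadjacent"` makes numerator and
#' denominator use the same universe.
#'
#' @param fit a [dcons()] fit.
#' @param denominator `"all"` (default) or `"nonadjacent"`.
#' @return data.frame with `label`, `count_top`, `count_all`, `ratio`
#'   (28 rows, canonical order). `sum(count_top)` equals the top-N size and
#'   `sum(count_all)` the scoreable-pair universe (under `"all"`).
#' @export
summarize_helix_pairs <- function(fit, denominator = c("all", "nonadjacent")) {
  .bin_counts(fit, "helix_pair", match.arg(denominator))
}

#' Section-pair decomposition of the top-ranked population
#'
#' Bins the top-N pairs into the 630 unordered section pairs over the 35
#' helix sections (105 intrahelical + 525 interhelical) and normalises by the
#' possible-pair totals, which for full default helices range from 9
#' (I.1 x VII.5, 3 x 3 positions) to 90 (VI.1 x VII.1, 10 x 9).
#'
#' When `helix_filter` names an intrahelical pair and `others = TRUE`, the
#' result mirrors the conventional table layout: the distinct-section pairs
#' are listed individually along with any same-section pair that contributed
#' to the top-N, the remaining same-section pairs are collapsed into an
#' `"others"` row, and a `"total"` row is appended.
#'
#' @param fit a [dcons()] fit.
#' @param helix_filter optional helix-pair label (e.g. `"III-III"`, `"I-VI"`)
#'   restricting the rows.
#' @param others collapse unlisted same-section pairs into an `"others"` row
#'   and append a total (defaults to `TRUE` when an intrahelical filter is
#'   given).
#' @inheritParams summarize_helix_pairs
#' @return data.frame with `label`, `section_a`, `section_b`, `count_top`,
#'   `count_all`, `ratio`.
#' @export
summarize_section_pairs <- function(fit, helix_filter = NULL,
                                    others = NULL,
                                    denominator = c("all", "nonadjacent")) {
  denominator <- match.arg(denominator)
  sp <- .bin_counts(fit, "section_pair", denominator)
  labs <- pair_labels(fit$defn)
  parts <- strsplit(sp$label, "-", fixed = TRUE)
  sp$section_a <- vapply(parts, `[`, "", 1L)
  sp$section_b <- vapply(parts, `[`, "", 2L)
  ha <- sub("\\..*$", "", sp$section_a)
  hb <- sub("\\..*$", "", sp$section_b)
  if (!is.null(helix_filter)) {
    if (!helix_filter %in% labs$helix_pairs) {
      stop("unknown helix pair '", helix_filter, "'; expected one of ",
           paste(labs$helix_pairs, collapse = ", "))
    }
    want <- strsplit(helix_filter, "-", fixed = TRUE)[[1]]
    sp <- sp[(ha == want[1] & hb == want[2]) |
               (ha == want[2] & hb == want[1]), , drop = FALSE]
    intra <- want[1] == want[2]
    if (is.null(others)) others <- intra
    if (others && intra) {
      same <- sub("^.*\\.", "", sp$section_a) == sub("^.*\\.", "", sp$section_b)
      keep <- !same | sp$count_top > 0
      shown <- sp[keep, , drop = FALSE]
      rest <- sp[!keep, , drop = FALSE]
      oth <- data.frame(label = "others", section_a = NA, section_b = NA,
                        count_top = sum(rest$count_top),
                        count_all = sum(rest$count_all),
                        ratio = if (sum(rest$count_all) > 0)
                          sum(rest$count_top) / sum(rest$count_all) else NA_real_,
                        stringsAsFactors = FALSE)
      tot <- data.frame(label = "total", section_a = NA, section_b = NA,
                        count_top = sum(sp$count_top),
                        count_all = sum(sp$count_all),
                        ratio = sum(sp$count_top) / sum(sp$count_all),
                        stringsAsFactors = FALSE)
      sp <- rbind(shown, oth, tot)
    }
  }
  rownames(sp) <- NULL
  sp
}

#' Cumulative bin counts over the ranked list
#'
#' For each bin, the cumulative number (and ratio to the bin total) of its
#' pairs encountered while walking the ranking from rank 1 to the top-N
#' cutoff — the data behind cumulative-contribution plots.
#'
#' @param fit a [dcons()] fit.
#' @param by `"helix_pair"` or `"section_pair"`.
#' @inheritParams summarize_helix_pairs
#' @return data.frame in long format: `rank`, `label`, `cum_count`,
#'   `cum_ratio`.
#' @export
cumulative_bin_counts <- function(fit, by = c("helix_pair", "section_pair"),
                                  denominator = c("all", "nonadjacent")) {
  by <- match.arg(by)
  denominator <- match.arg(denominator)
  totals <- .bin_counts(fit, by, denominator)
  tot <- stats::setNames(totals$count_all, totals$label)
  top <- fit$top
  labs <- unique(top[[by]])
  out <- do.call(rbind, lapply(labs, function(l) {
    hit <- cumsum(top[[by]] == l)
    data.frame(rank = top$rank, label = l, cum_count = hit,
               cum_ratio = if (tot[[l]] > 0) hit / tot[[l]] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare bin summaries across ensemble sets
#'
#' Aligns two or more summaries (from [summarize_helix_pairs()] or
#' [summarize_section_pairs()]) on their bin labels and reports per-bin ratio
#' differences relative to the first (reference) set, sorted by decreasing
#' absolute difference — the leave-subfamily-out comparison.
#'
#' @param summaries named list of summary data.frames sharing one bundle
#'   definition (>= 2).
#' @return data.frame with `label`, one `ratio_<name>` column per set, and
#'   one `delta_<name>` column per non-reference set (`ratio_<name>` minus
#'   the reference ratio).
#' @export
compare_sets <- function(summaries) {
  stopifnot(is.list(summaries), length(summaries) >= 2)
  nm <- names(summaries)
  if (is.null(nm) || any(nm == "")) {
    stop("summaries must be a named list")
  }
  ref <- summaries[[1]]
  for (s in summaries[-1]) {
    if (!identical(s$label, ref$label)) {
      stop("bin labels differ between sets; summaries must share a bundle ",
           "definition and layout")
    }
  }
  out <- data.frame(label = ref$label, stringsAsFactors = FALSE)
  for (i in seq_along(summaries)) {
    out[[paste0("ratio_", nm[i])]] <- summaries[[i]]$ratio
  }
  dmax <- rep(0, nrow(out))
  for (i in seq_along(summaries)[-1]) {
    d <- summaries[[i]]$ratio - ref$ratio
    out[[paste0("delta_", nm[i])]] <- d
    dmax <- pmax(dmax, abs(d), na.rm = TRUE)
  }
  out <- out[order(-dmax), , drop = FALSE]
  rownames(out) <- NULL
  out
}
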