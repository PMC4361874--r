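# Ballesteros-Weinstein coordinate frame for a 7TM bundle:
# positions, per-helix ranges, the 5-section partition, pair enumeration,
# adjacency and helix-/section-pair classification.

.ROMAN <- c("I", "II", "III", "IV", "V", "VI", "VII")

#' Ballesteros-Weinstein position identifiers
#'
#' A BW position is written `"<helix>.<index>"` (e.g. `"3.50"`, the most
#' conserved position of helix III). Internally positions are packed into an
#' integer id `helix * 100 + index`, which sorts by helix and then by index.
#'
#' @param helix integer vector, helix number 1-7.
#' @param index integer vector, BW index within the helix (two digits,
#'   serially numbered in both directions from the `*.50` anchor).
#' @return `bw_id()` returns integer ids; `bw_chr()` formats ids as
#'   `"h.ii"` strings; `bw_parse()` converts strings back to ids;
#'   `bw_helix()` and `bw_index()` extract the two fields.
#' @examples
#' bw_id(3, 50)
#' bw_chr(bw_id(3, 50))
#' bw_parse("6.50")
#' @export
bw_id <- function(helix, index) {
  helix <- as.integer(helix)
  index <- as.integer(index)
  stopifnot(all(helix >= 1L & helix <= 7L), all(index >= 1L & index <= 99L))
  helix * 100L + index
}

#' @rdname bw_id
#' @param id integer BW id as returned by [bw_id()].
#' @export
bw_helix <- function(id) id %/% 100L

#' @rdname bw_id
#' @export
bw_index <- function(id) id %% 100L

#' @rdname bw_id
#' @export
bw_chr <- function(id) sprintf("%d.%02d", bw_helix(id), bw_index(id))

#' @rdname bw_id
#' @param x character vector of `"h.ii"` strings.
#' @export
bw_parse <- function(x) {
  m <- regmatches(x, regexec("^([1-7])\\.([0-9]{1,2})$", as.character(x)))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("invalid BW position string(s): ", paste(x[bad], collapse = ", "))
  }
  bw_id(vapply(m, `[`, "", 2L), vapply(m, `[`, "", 3L))
}

roman_helix <- function(helix) .ROMAN[helix]

#' Define a 7TM bundle frame
#'
#' A bundle definition fixes, for each of the seven transmembrane helices,
#' the inclusive BW index range, the membrane orientation (which end of the
#' index range is extracellular), and the sizes of the five contiguous
#' sections that partition the helix. Sections are always numbered 1
#' (extracellular) to 5 (intracellular); because the helices alternate
#' direction across the membrane, section 1 sits at the low-index end of
#' odd-direction helices and at the high-index end of the others.
#'
#' @param helices data.frame with columns `helix` (1-7), `start`, `end`
#'   (inclusive BW indices) and `ec_end` (`"first"` if the lowest BW index is
#'   the extracellular end, `"last"` otherwise).
#' @param section_sizes 7 x 5 integer matrix; row h gives the sizes of
#'   sections 1-5 of helix h. Each row must sum to the helix length.
#' @return An object of class `bundle_definition` with a `positions`
#'   data.frame (`id`, `bw`, `helix`, `index`, `section`, `section_label`).
#' @seealso [default_bundle()] for the shipped 200-position frame,
#'   [load_bundle_definition()] to read one from a YAML config.
#' @export
bundle_definition <- function(helices, section_sizes) {
  stopifnot(is.data.frame(helices),
            all(c("helix", "start", "end", "ec_end") %in% names(helices)))
  helices <- helices[order(helices$helix), , drop = FALSE]
  if (!identical(as.integer(helices$helix), 1:7)) {
    stop("bundle definition must list each helix 1-7 exactly once")
  }
  if (!all(helices$ec_end %in% c("first", "last"))) {
    stop("ec_end must be 'first' or 'last' for every helix")
  }
  section_sizes <- matrix(as.integer(section_sizes), nrow = 7, ncol = 5)
  len <- helices$end - helices$start + 1L
  if (any(len < 5L)) stop("every helix needs at least 5 positions")
  if (any(section_sizes < 1L)) {
    bad <- which(rowSums(section_sizes < 1L) > 0)
    stop("empty section(s) in helix ", paste(roman_helix(bad), collapse = ", "))
  }
  ssum <- rowSums(section_sizes)
  if (any(ssum != len)) {
    bad <- which(ssum != len)
    stop("section sizes do not cover helix ",
         paste(sprintf("%s (sum %d, length %d)", roman_helix(bad),
                       ssum[bad], len[bad]), collapse = "; "))
  }

  pos <- do.call(rbind, lapply(1:7, function(h) {
    idx <- seq.int(helices$start[h], helices$end[h])
    sizes <- section_sizes[h, ]
    # section 1 = extracellular: along increasing BW index the sections run
    # 1..5 when the low-index end is extracellular, 5..1 otherwise
    sec_along <- rep.int(1:5, sizes)
    if (helices$ec_end[h] == "last") sec_along <- rep.int(5:1, sizes[5:1])
    data.frame(id = bw_id(h, idx), helix = h, index = idx,
               section = sec_along)
  }))
  pos$bw <- bw_chr(pos$id)
  pos$section_label <- sprintf("%s.%d", roman_helix(pos$helix), pos$section)
  pos <- pos[order(pos$id), c("id", "bw", "helix", "index", "section",
                              "section_label")]
  rownames(pos) <- NULL

  structure(list(helices = helices, section_sizes = section_sizes,
                 positions = pos),
            class = "bundle_definition")
}

#' The default 200-position 7TM bundle frame
#'
#' Seven helices totalling 200 BW positions with five sections each (35
#' sections in all). Helix III spans 3.22-3.55 (34 positions) with section
#' sizes 8, 8, 4, 7, 7; section 1 of helix I and section 5 of helix VII hold
#' 3 positions each; section 1 of helices VI and VII hold 10 and 9. The
#' remaining ranges and boundaries are package defaults consistent with
#' standard BW helix spans; all are editable through
#' [load_bundle_definition()].
#'
#' @return A [bundle_definition()].
#' @examples
#' defn <- default_bundle()
#' nrow(defn$positions)          # 200
#' sum(defn$positions$helix == 3) # 34
#' @export
default_bundle <- function() {
  helices <- data.frame(
    helix = 1:7,
    start = c(30L, 38L, 22L, 39L, 36L, 30L, 33L),
    end   = c(60L, 67L, 55L, 62L, 64L, 60L, 53L),
    ec_end = c("first", "last", "first", "last", "first", "last", "first"),
    stringsAsFactors = FALSE
  )
  sizes <- rbind(
    c(3L, 7L, 7L, 7L, 7L),   # I   (31)
    c(6L, 6L, 6L, 6L, 6L),   # II  (30)
    c(8L, 8L, 4L, 7L, 7L),   # III (34)
    c(5L, 5L, 5L, 5L, 4L),   # IV  (24)
    c(6L, 6L, 6L, 6L, 5L),   # V   (29)
    c(10L, 6L, 5L, 5L, 5L),  # VI  (31)
    c(9L, 3L, 3L, 3L, 3L)    # VII (21)
  )
  bundle_definition(helices, sizes)
}

#' Read a bundle definition from a YAML config
#'
#' The config lists the seven helices with their BW ranges, section sizes and
#' membrane orientation:
#' ```yaml
#' helices:
#'   - {helix: 3, start: 22, end: 55, sections: [8, 8, 4, 7, 7],
#'      extracellular_end: first}
#'   ...
#' ```
#'
#' @param path path to the YAML file.
#' @return A validated [bundle_definition()]; invalid configs (wrong helix
#'   set, sections that do not exactly cover a range) raise errors naming
#'   the offending helix.
#' @export
load_bundle_definition <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$helices)) stop("config has no 'helices' key: ", path)
  hl <- cfg$helices
  if (length(hl) != 7L) stop("config must define exactly 7 helices, found ",
                             length(hl))
  helices <- data.frame(
    helix = vapply(hl, function(h) as.integer(h$helix), 1L),
    start = vapply(hl, function(h) as.integer(h$start), 1L),
    end   = vapply(hl, function(h) as.integer(h$end), 1L),
    ec_end = vapply(hl, function(h) {
      e <- h$extracellular_end
      if (is.null(e)) e <- h$ec_end
      as.character(e)
    }, ""),
    stringsAsFactors = FALSE
  )
  sizes <- do.call(rbind, lapply(hl, function(h) {
    s <- as.integer(h$sections)
    if (length(s) != 5L) {
      stop("helix ", h$helix, ": expected 5 section sizes, got ", length(s))
    }
    s
  }))
  sizes <- sizes[order(helices$helix), , drop = FALSE]
  bundle_definition(helices, sizes)
}

#' @export
print.bundle_definition <- function(x, ...) {
  cat("7TM bundle definition:", nrow(x$positions), "BW positions\n")
  h <- x$helices
  for (i in 1:7) {
    cat(sprintf("  %-4s %d.%02d-%d.%02d (%2d)  sections %s  EC end: %s\n",
                roman_helix(i), i, h$start[i], i, h$end[i],
                h$end[i] - h$start[i] + 1L,
                paste(x$section_sizes[i, ], collapse = ","),
                h$ec_end[i]))
  }
  invisible(x)
}

#' All BW positions of a bundle definition
#'
#' @param defn a [bundle_definition()].
#' @return integer vector of BW ids, sorted.
#' @export
bw_positions <- function(defn) {
  stopifnot(inherits(defn, "bundle_definition"))
  defn$positions$id
}

#' Enumerate unordered position pairs
#'
#' All unordered pairs of distinct BW positions from `present`, each stored
#' canonically with `a < b`. For `n` present positions this yields
#' `n (n - 1) / 2` pairs: 19,900 for the full 200-position frame, 19,701
#' when one position is absent, 18,915 when five are.
#'
#' @param defn a [bundle_definition()].
#' @param present integer vector of BW ids to pair up; defaults to every
#'   position of `defn`.
#' @return data.frame with integer columns `a`, `b` (canonical, `a < b`).
#' @export
enumerate_pairs <- function(defn, present = NULL) {
  stopifnot(inherits(defn, "bundle_definition"))
  all_pos <- defn$positions$id
  if (is.null(present)) present <- all_pos
  present <- sort(unique(as.integer(present)))
  if (length(present) == 0L) stop("present-position set is empty")
  if (!all(present %in% all_pos)) {
    stop("positions outside the bundle definition: ",
         paste(bw_chr(setdiff(present, all_pos)), collapse = ", "))
  }
  n <- length(present)
  if (n < 2L) stop("need at least 2 positions to form pairs")
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  data.frame(a = present[i], b = present[j])
}

#' Sequence adjacency of a position pair
#'
#' Two positions are adjacent when they are consecutive BW indices within
#' the same helix (the ~3.8 A backbone neighbours whose distance is trivially
#' invariant). Pairs spanning a helix junction are not adjacent, so the full
#' 200-position frame has 199 - 6 = 193 adjacent pairs.
#'
#' @param a,b integer BW ids (vectorised).
#' @param defn a [bundle_definition()] (positions must belong to it).
#' @return logical vector.
#' @export
is_adjacent <- function(a, b, defn) {
  stopifnot(inherits(defn, "bundle_definition"))
  ok <- c(a, b) %in% defn$positions$id
  if (!all(ok)) stop("position(s) outside the bundle definition")
  bw_helix(a) == bw_helix(b) & abs(bw_index(a) - bw_index(b)) == 1L
}

#' Classify a position pair by helix pair and section pair
#'
#' Every unordered pair maps to one of 28 helix-pair labels (7 intrahelical +
#' 21 interhelical, e.g. `"III-III"`, `"I-VI"`) and one of 630 section-pair
#' labels over the 35 sections (105 intrahelical + 525 interhelical, e.g.
#' `"I.4-VI.2"`). Labels are canonical: the lower (helix, section) member
#' comes first.
#'
#' @param a,b integer BW ids (vectorised).
#' @param defn a [bundle_definition()].
#' @return data.frame with columns `helix_pair` and `section_pair`.
#' @export
classify_pair <- function(a, b, defn) {
  stopifnot(inherits(defn, "bundle_definition"))
  pos <- defn$positions
  ia <- match(a, pos$id)
  ib <- match(b, pos$id)
  if (anyNA(ia) || anyNA(ib)) stop("position(s) outside the bundle definition")
  ha <- pos$helix[ia]; hb <- pos$helix[ib]
  sa <- pos$section[ia]; sb <- pos$section[ib]
  # canonical order by (helix, section)
  ka <- ha * 10L + sa; kb <- hb * 10L + sb
  swap <- ka > kb
  h1 <- ifelse(swap, hb, ha); h2 <- ifelse(swap, ha, hb)
  s1 <- ifelse(swap, sb, sa); s2 <- ifelse(swap, sa, sb)
  data.frame(
    helix_pair = sprintf("%s-%s", roman_helix(pmin(ha, hb)),
                         roman_helix(pmax(ha, hb))),
    section_pair = sprintf("%s.%d-%s.%d", roman_helix(h1), s1,
                           roman_helix(h2), s2),
    stringsAsFactors = FALSE
  )
}

#' All helix-pair and section-pair labels of a bundle frame
#'
#' @param defn a [bundle_definition()].
#' @return list with `helix_pairs` (28 labels) and `section_pairs`
#'   (630 labels), each in canonical order, plus `section_pair_sizes`, the
#'   total number of position pairs each section pair admits over the full
#'   frame (C(size, 2) on the diagonal, size x size off it).
#' @export
pair_labels <- function(defn) {
  stopifnot(inherits(defn, "bundle_definition"))
  hp <- character(0)
  for (i in 1:7) for (j in i:7) {
    hp <- c(hp, sprintf("%s-%s", roman_helix(i), roman_helix(j)))
  }
  secs <- expand.grid(section = 1:5, helix = 1:7)[, c("helix", "section")]
  lab <- sprintf("%s.%d", roman_helix(secs$helix), secs$section)
  size <- defn$section_sizes[cbind(secs$helix, secs$section)]
  sp <- character(0); sz <- numeric(0); intra <- logical(0)
  for (i in seq_len(35)) for (j in i:35) {
    sp <- c(sp, paste0(lab[i], "-", lab[j]))
    sz <- c(sz, if (i == j) choose(size[i], 2) else size[i] * size[j])
    intra <- c(intra, secs$helix[i] == secs$helix[j])
  }
  list(helix_pairs = hp, section_pairs = sp,
       section_pair_sizes = stats::setNames(sz, sp),
       section_pair_intrahelical = stats::setNames(intra, sp))
}

# Full per-pair annotation table used by scoring: canonical pairs over the
# present positions plus adjacency and classification columns.
pair_table <- function(defn, present = NULL) {
  pr <- enumerate_pairs(defn, present)
  cls <- classify_pair(pr$a, pr$b, defn)
  pr$bw_a <- bw_chr(pr$a)
  pr$bw_b <- bw_chr(pr$b)
  pr$helix_pair <- cls$helix_pair
  pr$section_pair <- cls$section_pair
  pr$adjacent <- is_adjacent(pr$a, pr$b, defn)
  pr
}
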