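# Structure input: PDB/mmCIF chain reading (via bio3d), BW alignment of
# backbone coordinates, and ensemble-set construction.

#' Construct an aligned bundle in code
#'
#' An aligned bundle holds one chain's backbone coordinates indexed by BW
#' position. Most users build these with [apply_alignment()] from a parsed
#' structure; this constructor is the programmatic route (used heavily by the
#' synthetic generator and in tests).
#'
#' @param ca numeric matrix (n x 3) of C-alpha coordinates in Angstrom with
#'   rownames equal to BW ids (see [bw_id()]).
#' @param defn the governing [bundle_definition()].
#' @param n,c optional matrices of backbone N and C coordinates, same
#'   rowname convention (needed for torsion analysis).
#' @param b optional named numeric vector of C-alpha temperature factors.
#' @param source_id,chain_id identifying labels.
#' @return An object of class `aligned_bundle` with elements `ca`, `n`, `c`,
#'   `b`, `present` (sorted BW ids with coordinates) and `missing` (BW ids of
#'   the definition absent from this chain).
#' @export
aligned_bundle <- function(ca, defn, n = NULL, c = NULL, b = NULL,
                           source_id = "unknown", chain_id = "A") {
  stopifnot(inherits(defn, "bundle_definition"), is.matrix(ca), ncol(ca) == 3)
  ids <- as.integer(rownames(ca))
  if (anyNA(ids)) stop("ca rownames must be integer BW ids")
  if (anyDuplicated(ids)) stop("duplicate BW positions in ca")
  all_pos <- defn$positions$id
  if (!all(ids %in% all_pos)) {
    stop("coordinates outside the bundle definition: ",
         paste(bw_chr(setdiff(ids, all_pos)), collapse = ", "))
  }
  if (!all(is.finite(ca))) stop("non-finite C-alpha coordinates")
  o <- order(ids)
  ca <- ca[o, , drop = FALSE]
  ids <- ids[o]
  dimnames(ca) <- list(ids, NULL)
  chk <- function(m, what) {
    if (is.null(m)) return(NULL)
    stopifnot(is.matrix(m), ncol(m) == 3)
    if (!all(is.finite(m))) stop("non-finite ", what, " coordinates")
    mi <- as.integer(rownames(m))
    if (!all(mi %in% ids)) stop(what, " coordinates at positions without CA")
    m <- m[order(mi), , drop = FALSE]
    dimnames(m) <- list(sort(mi), NULL)
    m
  }
  n <- chk(n, "N"); c <- chk(c, "C")
  if (!is.null(b)) {
    bi <- as.integer(names(b))
    if (!all(bi %in% ids)) stop("B-factors at positions without CA")
    b <- b[order(bi)]
  }
  structure(list(source_id = source_id, chain_id = chain_id,
                 ca = ca, n = n, c = c, b = b,
                 present = ids, missing = setdiff(all_pos, ids)),
            class = "aligned_bundle")
}

#' @export
print.aligned_bundle <- function(x, ...) {
  cat(sprintf("aligned 7TM bundle %s chain %s: %d positions present, %d missing%s\n",
              x$source_id, x$chain_id, length(x$present), length(x$missing),
              if (is.null(x$n)) " (CA only)" else " (N/CA/C)"))
  if (length(x$missing) > 0 && length(x$missing) <= 12) {
    cat("  missing:", paste(bw_chr(x$missing), collapse = " "), "\n")
  }
  invisible(x)
}

#' Read one chain's backbone records from a PDB or mmCIF file
#'
#' Extracts per-residue backbone atom records (N, CA, C) for a single chain.
#' Only the first model is used. When alternate conformers are present, only
#' conformer A (or the blank altloc) is retained, regardless of record order.
#' Residues lacking a C-alpha are dropped with a warning; they surface later
#' in an aligned bundle's `missing` set.
#'
#' @param path PDB (`.pdb`/`.ent`) or mmCIF (`.cif`) file.
#' @param chain_id one-letter chain identifier.
#' @return data.frame with columns `resno`, `insert`, `elety`, `x`, `y`, `z`,
#'   `b`; one row per retained backbone atom.
#' @export
read_chain <- function(path, chain_id) {
  if (!file.exists(path)) stop("no such structure file: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, verbose = FALSE)
  }
  at <- pdb$atom
  if (!chain_id %in% unique(at$chain)) {
    stop("chain '", chain_id, "' not found in ", basename(path),
         "; available: ", paste(sort(unique(at$chain)), collapse = ", "))
  }
  at <- at[at$chain == chain_id & at$type == "ATOM" &
             at$elety %in% c("N", "CA", "C"), , drop = FALSE]
  # altloc rule: keep blank/NA or conformer A only
  alt <- at$alt
  at <- at[is.na(alt) | alt %in% c("", "A"), , drop = FALSE]
  ins <- at$insert
  ins[is.na(ins)] <- ""
  rec <- data.frame(resno = at$resno, insert = ins, elety = at$elety,
                    x = at$x, y = at$y, z = at$z, b = at$b,
                    stringsAsFactors = FALSE)
  # drop duplicate atoms within a residue (shouldn't occur after altloc rule)
  key <- paste(rec$resno, rec$insert, rec$elety)
  rec <- rec[!duplicated(key), , drop = FALSE]
  # residues with no CA cannot be placed in the bundle
  has_ca <- paste(rec$resno, rec$insert) %in%
    paste(rec$resno, rec$insert)[rec$elety == "CA"]
  if (any(!has_ca)) {
    warning(sum(!has_ca), " backbone atom(s) in residues lacking CA dropped")
    rec <- rec[has_ca, , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

#' Read a residue-to-BW alignment table
#'
#' Tab-separated with columns `source_id`, `chain_id`, `residue` (residue
#' number, optionally with an insertion-code suffix, e.g. `100A`) and
#' `bw_position` (`"h.ii"`).
#'
#' @param path TSV file.
#' @return data.frame with those columns plus an integer `bw` id column.
#' @export
read_alignment_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("source_id", "chain_id", "residue", "bw_position")
  if (!all(need %in% names(tab))) {
    stop("alignment table must have columns ", paste(need, collapse = ", "))
  }
  tab$bw <- bw_parse(tab$bw_position)
  tab
}

#' Map chain records onto the BW frame
#'
#' @param records backbone records from [read_chain()].
#' @param alignment either a named map (names = residue keys such as `"123"`
#'   or `"100A"` for insertion codes, values = BW ids or `"h.ii"` strings) or
#'   a data.frame with columns `residue` and `bw` / `bw_position`.
#' @param defn the governing [bundle_definition()].
#' @param source_id,chain_id labels stored on the result.
#' @return An [aligned_bundle()]. Residues not named in the alignment are
#'   ignored; mapped positions without a modelled residue populate the
#'   `missing` set. Two residues mapped to one BW position is an error.
#' @export
apply_alignment <- function(records, alignment, defn,
                            source_id = "unknown", chain_id = "A") {
  stopifnot(inherits(defn, "bundle_definition"))
  if (is.data.frame(alignment)) {
    bwv <- if ("bw" %in% names(alignment)) alignment$bw
           else bw_parse(alignment$bw_position)
    alignment <- stats::setNames(bwv, as.character(alignment$residue))
  }
  if (is.character(alignment)) alignment <- bw_parse(alignment)
  bw <- as.integer(alignment)
  keys <- names(alignment)
  if (is.null(keys)) stop("alignment must be keyed by residue number")
  if (anyDuplicated(bw)) {
    dup <- bw[duplicated(bw)]
    stop("two residues mapped to one BW position: ",
         paste(bw_chr(unique(dup)), collapse = ", "))
  }
  if (!all(bw %in% defn$positions$id)) {
    stop("alignment maps outside the bundle definition: ",
         paste(bw_chr(setdiff(bw, defn$positions$id)), collapse = ", "))
  }
  reskey <- paste0(records$resno, records$insert)
  pick <- function(elety) {
    sub <- records[records$elety == elety, , drop = FALSE]
    k <- paste0(sub$resno, sub$insert)
    hit <- match(keys, k)
    ok <- !is.na(hit)
    m <- as.matrix(sub[hit[ok], c("x", "y", "z")])
    rownames(m) <- bw[ok]
    list(m = m, ok = ok, rows = hit[ok])
  }
  ca <- pick("CA")
  if (nrow(ca$m) == 0L) stop("no aligned C-alpha atoms for this chain")
  bvals <- records$b[records$elety == "CA"][ca$rows]
  names(bvals) <- rownames(ca$m)
  nn <- pick("N"); cc <- pick("C")
  # N/C kept only at positions that also have a CA
  keep <- function(p) {
    if (nrow(p$m) == 0L) return(NULL)
    p$m[rownames(p$m) %in% rownames(ca$m), , drop = FALSE]
  }
  aligned_bundle(ca$m, defn, n = keep(nn), c = keep(cc), b = bvals,
                 source_id = source_id, chain_id = chain_id)
}

#' Mean C-alpha temperature factor of a bundle
#'
#' Arithmetic mean over the present positions; used to pick, among chains of
#' one entry, the one with the lowest overall C-alpha B-factor.
#'
#' @param bundle an [aligned_bundle()].
#' @return numeric scalar.
#' @export
mean_ca_bfactor <- function(bundle) {
  stopifnot(inherits(bundle, "aligned_bundle"))
  if (is.null(bundle$b)) stop("bundle carries no B-factors")
  mean(bundle$b)
}

#' Assemble an ensemble set of aligned bundles
#'
#' The scoreable pair universe of a set is defined over the positions present
#' in every member (the intersection), so a single member lacking one
#' position shrinks the universe for the whole set: 199 common positions give
#' 19,701 pairs, 195 give 18,915.
#'
#' @param members list of [aligned_bundle()] objects (at least 2).
#' @param name set label.
#' @param defn optional [bundle_definition()] for validation.
#' @return An object of class `bundle_ensemble` with `members`,
#'   `common` (intersection of present BW ids) and `name`.
#' @export
build_set <- function(members, name = "set", defn = NULL) {
  if (!is.list(members) || length(members) < 2L) {
    stop("an ensemble set needs at least 2 members")
  }
  if (!all(vapply(members, inherits, TRUE, "aligned_bundle"))) {
    stop("all members must be aligned_bundle objects")
  }
  common <- Reduce(intersect, lapply(members, `[[`, "present"))
  if (!is.null(defn)) {
    stopifnot(inherits(defn, "bundle_definition"))
    if (!all(common %in% defn$positions$id)) {
      stop("members carry positions outside the bundle definition")
    }
  }
  if (length(common) < 2L) stop("fewer than 2 positions common to all members")
  structure(list(name = name, members = members, common = sort(common)),
            class = "bundle_ensemble")
}

#' @export
print.bundle_ensemble <- function(x, ...) {
  n <- length(x$common)
  cat(sprintf("7TM ensemble '%s': %d members, %d common positions (%d pairs)\n",
              x$name, length(x$members), n, n * (n - 1) / 2))
  invisible(x)
}
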