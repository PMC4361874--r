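# Pipeline stages behind the command-line entry point: each run_* function
# consumes files, writes plain TSV outputs with a provenance header, and
# records its resolved configuration alongside the outputs.

pkg_version <- function() {
  as.character(utils::packageVersion("caconserve"))
}

# resolved-config writer: deterministic YAML + md5 for provenance headers
write_config <- function(cfg, out_dir, stage) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, sprintf("config_%s.yaml", stage))
  cfg <- cfg[order(names(cfg))]
  writeLines(yaml::as.yaml(cfg), path)
  unname(tools::md5sum(path))
}

write_tsv_prov <- function(df, path, config_md5) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# caconserve %s", pkg_version()),
               sprintf("# config_md5: %s", config_md5)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_prov <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

resolve_defn <- function(defn) {
  if (inherits(defn, "bundle_definition")) return(defn)
  if (is.character(defn)) return(load_bundle_definition(defn))
  if (is.null(defn)) return(default_bundle())
  stop("defn must be a bundle_definition or a config path")
}

# assemble the aligned bundles of one manifest set from structure files
load_set <- function(structures_dir, alignment, manifest, set_name,
                     defn = NULL) {
  defn <- resolve_defn(defn)
  align <- if (is.character(alignment)) read_alignment_table(alignment)
           else alignment
  man <- if (is.character(manifest)) {
    utils::read.delim(manifest, comment.char = "#", stringsAsFactors = FALSE)
  } else manifest
  man <- man[man$set_name == set_name, , drop = FALSE]
  if (nrow(man) == 0L) stop("no members of set '", set_name, "' in manifest")
  members <- lapply(seq_len(nrow(man)), function(i) {
    sid <- man$source_id[i]; cid <- man$chain_id[i]
    path <- file.path(structures_dir, paste0(sid, ".pdb"))
    if (!file.exists(path)) path <- file.path(structures_dir,
                                              paste0(sid, ".cif"))
    rec <- read_chain(path, cid)
    al <- align[align$source_id == sid & align$chain_id == cid, , drop = FALSE]
    apply_alignment(rec, stats::setNames(al$bw, al$residue), defn,
                    source_id = sid, chain_id = cid)
  })
  build_set(members, name = set_name, defn = defn)
}

#' Pipeline stage: simulate a synthetic ensemble to disk
#'
#' Generates a synthetic 7TM ensemble (see [generate_ensemble()]) and writes
#' the PDB fixtures, alignment table and set manifest under
#' `out_dir/structures`, plus the resolved configuration.
#'
#' @param out_dir output directory.
#' @param preset_name preset passed to [preset()]; ignored when `spec` given.
#' @param seed integer seed.
#' @param n_members optional member-count override.
#' @param spec optional explicit [generator_spec()].
#' @param defn bundle definition (object or config path; default frame).
#' @param set_name manifest set name.
#' @return the generated ensemble, invisibly.
#' @export
run_simulate <- function(out_dir, preset_name = "rhodopsin_like", seed = 1L,
                         n_members = NULL, spec = NULL, defn = NULL,
                         set_name = preset_name) {
  defn <- resolve_defn(defn)
  if (is.null(spec)) spec <- preset(preset_name, n_members = n_members,
                                    seed = seed)
  sdir <- file.path(out_dir, "structures")
  ens <- generate_ensemble(spec, defn, dir = sdir, name = set_name)
  cfg <- list(stage = "simulate", preset = preset_name, seed = spec$seed,
              n_members = spec$n_members, set_name = set_name,
              structures = "structures")
  write_config(cfg, out_dir, "simulate")
  invisible(ens)
}

#' Pipeline stage: extract aligned bundles to per-chain tables
#'
#' Reads every (source, chain) of the alignment table from `structures_dir`,
#' maps it onto the BW frame and persists one TSV per chain (`bw`, `x`, `y`,
#' `z`, `b`) under `out_dir/bundles`. Chains missing more than
#' `max_missing_frac` of the bundle positions are rejected with an explicit
#' count.
#'
#' @param structures_dir directory of PDB/mmCIF files named `<source_id>.pdb`.
#' @param alignment path to the alignment TSV (see [read_alignment_table()]).
#' @param out_dir output directory.
#' @param defn bundle definition (object or config path).
#' @param max_missing_frac rejection threshold (default 0.5).
#' @return data.frame index of extracted chains, invisibly.
#' @export
run_extract <- function(structures_dir, alignment, out_dir, defn = NULL,
                        max_missing_frac = 0.5) {
  defn <- resolve_defn(defn)
  align <- read_alignment_table(alignment)
  # configs record basenames so identical runs rooted elsewhere stay
  # byte-identical
  cfg <- list(stage = "extract", structures_dir = basename(structures_dir),
              alignment = basename(alignment),
              max_missing_frac = max_missing_frac,
              n_positions = nrow(defn$positions))
  md5 <- write_config(cfg, out_dir, "extract")
  bdir <- file.path(out_dir, "bundles")
  dir.create(bdir, showWarnings = FALSE, recursive = TRUE)
  chains <- unique(align[, c("source_id", "chain_id")])
  idx <- NULL
  for (i in seq_len(nrow(chains))) {
    sid <- chains$source_id[i]; cid <- chains$chain_id[i]
    path <- file.path(structures_dir, paste0(sid, ".pdb"))
    if (!file.exists(path)) path <- file.path(structures_dir,
                                              paste0(sid, ".cif"))
    rec <- read_chain(path, cid)
    al <- align[align$source_id == sid & align$chain_id == cid, , drop = FALSE]
    bun <- apply_alignment(rec, stats::setNames(al$bw, al$residue), defn,
                           source_id = sid, chain_id = cid)
    n_all <- nrow(defn$positions)
    if (length(bun$missing) > max_missing_frac * n_all) {
      stop(sprintf("chain %s:%s rejected: %d of %d bundle positions missing",
                   sid, cid, length(bun$missing), n_all))
    }
    tab <- data.frame(bw = bw_chr(bun$present),
                      x = bun$ca[, 1], y = bun$ca[, 2], z = bun$ca[, 3],
                      b = if (is.null(bun$b)) NA_real_ else bun$b)
    out <- file.path(bdir, sprintf("%s_%s.tsv", sid, cid))
    write_tsv_prov(tab, out, md5)
    idx <- rbind(idx, data.frame(source_id = sid, chain_id = cid,
                                 n_present = length(bun$present),
                                 n_missing = length(bun$missing),
                                 file = basename(out)))
  }
  write_tsv_prov(idx, file.path(out_dir, "bundles_index.tsv"), md5)
  invisible(idx)
}

#' Pipeline stage: score an ensemble set
#'
#' Loads the members of one manifest set, fits [dcons()] and writes
#' `pair_stats.tsv` (every scoreable pair with mean/sd/min/max/score and the
#' rank it received, `NA` for pairs outside the ranking) and
#' `score_profile.tsv` (binned score counts).
#'
#' @inheritParams run_extract
#' @param manifest path to the set-manifest TSV.
#' @param set_name which set to score.
#' @param top_n,exclude_adjacent see [dcons()].
#' @param score_bin histogram bin width in score units.
#' @return the [dcons()] fit, invisibly.
#' @export
run_score <- function(structures_dir, alignment, manifest, set_name, out_dir,
                      defn = NULL, top_n = 1000L, exclude_adjacent = TRUE,
                      score_bin = 5) {
  defn <- resolve_defn(defn)
  ens <- load_set(structures_dir, alignment, manifest, set_name, defn)
  fit <- dcons(ens, defn, top_n = top_n, exclude_adjacent = exclude_adjacent)
  cfg <- list(stage = "score", set_name = set_name, top_n = top_n,
              exclude_adjacent = exclude_adjacent,
              sd_convention = fit$sd_convention, score_cap = fit$score_cap,
              n_members = fit$n_members, universe = fit$universe)
  md5 <- write_config(cfg, out_dir, "score")
  tab <- fit$stats
  tab$rank <- fit$ranked$rank[match(paste(tab$a, tab$b),
                                    paste(fit$ranked$a, fit$ranked$b))]
  cols <- c("bw_a", "bw_b", "helix_pair", "section_pair", "mean", "sd",
            "min", "max", "score", "rank", "adjacent", "n_members")
  write_tsv_prov(tab[, cols], file.path(out_dir, "pair_stats.tsv"), md5)
  pf <- score_distance_profile(fit, score_bin = score_bin)
  write_tsv_prov(pf$score_hist, file.path(out_dir, "score_profile.tsv"), md5)
  invisible(fit)
}

#' Pipeline stage: classify the top-ranked population
#'
#' Bins the top-N pairs by helix pair and section pair with possible-pair
#' normalisation, writing `helix_pairs.tsv`, `section_pairs.tsv` and
#' `cumulative_helix_pairs.tsv`.
#'
#' @param pairs a [dcons()] fit or the path to a `pair_stats.tsv` written by
#'   [run_score()].
#' @param out_dir output directory.
#' @param defn bundle definition (object or config path); needed to label the
#'   bins when `pairs` is a file.
#' @param top_n top-N cutoff (applied to the stored ranks when reading a
#'   file).
#' @param helix_filter optional helix-pair label for a filtered section table
#'   (`section_pairs_<filter>.tsv`, with `others`/`total` rows for an
#'   intrahelical filter).
#' @param denominator see [summarize_helix_pairs()].
#' @return list of the summary data.frames, invisibly.
#' @export
run_classify <- function(pairs, out_dir, defn = NULL, top_n = 1000L,
                         helix_filter = NULL,
                         denominator = c("all", "nonadjacent")) {
  denominator <- match.arg(denominator)
  defn <- resolve_defn(defn)
  fit <- if (inherits(pairs, "dcons")) {
    pairs
  } else {
    tab <- read_tsv_prov(pairs)
    top <- tab[!is.na(tab$rank) & tab$rank <= top_n, , drop = FALSE]
    top <- top[order(top$rank), , drop = FALSE]
    structure(list(stats = tab, top = top, defn = defn,
                   universe = nrow(tab)), class = "dcons")
  }
  cfg <- list(stage = "classify", top_n = top_n, denominator = denominator,
              helix_filter = if (is.null(helix_filter)) "none"
                             else helix_filter)
  md5 <- write_config(cfg, out_dir, "classify")
  hp <- summarize_helix_pairs(fit, denominator = denominator)
  sp <- summarize_section_pairs(fit, denominator = denominator)
  write_tsv_prov(hp, file.path(out_dir, "helix_pairs.tsv"), md5)
  write_tsv_prov(sp, file.path(out_dir, "section_pairs.tsv"), md5)
  cum <- cumulative_bin_counts(fit, "helix_pair", denominator)
  write_tsv_prov(cum, file.path(out_dir, "cumulative_helix_pairs.tsv"), md5)
  out <- list(helix_pairs = hp, section_pairs = sp, cumulative = cum)
  if (!is.null(helix_filter)) {
    fs <- summarize_section_pairs(fit, helix_filter = helix_filter,
                                  denominator = denominator)
    write_tsv_prov(fs, file.path(out_dir,
                                 sprintf("section_pairs_%s.tsv",
                                         gsub("-", "_", helix_filter))), md5)
    out$filtered <- fs
  }
  invisible(out)
}

#' Pipeline stage: torsion deviations
#'
#' Computes per-position and per-section phi/psi circular deviations for one
#' manifest set, writing `torsion_positions.tsv` and `torsion_sections.tsv`.
#'
#' @inheritParams run_score
#' @param method deviation statistic, see [circ_dev()].
#' @return the [torsion_deviation()] object, invisibly.
#' @export
run_torsion <- function(structures_dir, alignment, manifest, set_name,
                        out_dir, defn = NULL, method = c("sd", "range")) {
  method <- match.arg(method)
  defn <- resolve_defn(defn)
  ens <- load_set(structures_dir, alignment, manifest, set_name, defn)
  td <- torsion_deviation(ens, defn, method = method)
  cfg <- list(stage = "torsion", set_name = set_name, method = method,
              n_members = td$n_members)
  md5 <- write_config(cfg, out_dir, "torsion")
  pos <- td$positions[, c("bw", "n_phi", "n_psi", "dev_phi", "dev_psi")]
  write_tsv_prov(pos, file.path(out_dir, "torsion_positions.tsv"), md5)
  write_tsv_prov(td$sections, file.path(out_dir, "torsion_sections.tsv"), md5)
  invisible(td)
}

#' Pipeline stage: compare bin summaries across sets
#'
#' @param summary_paths named character vector of `helix_pairs.tsv` /
#'   `section_pairs.tsv` paths (or a named list of summary data.frames).
#' @param out_dir output directory.
#' @return the [compare_sets()] table, invisibly.
#' @export
run_compare <- function(summary_paths, out_dir) {
  summaries <- if (is.character(summary_paths)) {
    stats::setNames(lapply(summary_paths, read_tsv_prov),
                    names(summary_paths))
  } else summary_paths
  cfg <- list(stage = "compare", sets = names(summaries))
  md5 <- write_config(cfg, out_dir, "compare")
  cmp <- compare_sets(summaries)
  write_tsv_prov(cmp, file.path(out_dir, "set_comparison.tsv"), md5)
  invisible(cmp)
}
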