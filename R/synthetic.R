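# Seeded generator of clade-structured protein families. Every default
# template shares the one synthetic NOX2-like scaffold and differs only in
# the residues planted at the seven reference positions (drawn from the
# signature table), EF-hand loops, and its domain layout — so generator truth
# and classifier rules share a single source.

#' Generator configuration
#'
#' @param n_per_clade Sequences per clade.
#' @param epsilon Per-site substitution rate in `[0, 0.2]`.
#' @param indel_rate Per-site deletion (gap) rate in `[0, 0.05]`; deletions
#'   never open at planted positions.
#' @param protect_planted Skip substitutions at planted sites (default TRUE).
#' @param seed Mandatory integer seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_per_clade, epsilon = 0.05, indel_rate = 0.01,
                             protect_planted = TRUE, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (epsilon < 0 || epsilon > 0.2)
    stop("substitution rate must be in [0, 0.2]")
  if (indel_rate < 0 || indel_rate > 0.05)
    stop("indel rate must be in [0, 0.05]")
  if (n_per_clade < 1) stop("n_per_clade must be >= 1")
  structure(list(n_per_clade = as.integer(n_per_clade), epsilon = epsilon,
                 indel_rate = indel_rate,
                 protect_planted = isTRUE(protect_planted),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Clade template for the synthetic generator
#'
#' @param name Clade label (used as truth label).
#' @param planted Named character vector: reference position -> residue.
#' @param scaffold Base amino-acid string (default: the synthetic NOX2-like
#'   reference scaffold).
#' @param ef_loop_starts Integer positions at which canonical EF-hand loops
#'   are written into the scaffold.
#' @param domain_layout Data frame `domain_name`, `start`, `end` (reference
#'   coordinates, non-overlapping, N-to-C).
#' @param nterm_extension Number of random residues prepended to every
#'   generated sequence (shifts all planted coordinates).
#' @param expected_label,expected_subtype,expected_architecture Truth values
#'   for benchmarking the classifiers.
#' @return List of class `clade_template`.
#' @export
clade_template <- function(name, planted,
                           scaffold = build_reference_scaffold(),
                           ef_loop_starts = integer(0),
                           domain_layout = NULL, nterm_extension = 0L,
                           expected_label = NA_character_,
                           expected_subtype = NA_character_,
                           expected_architecture = NA_character_) {
  residues <- strsplit(scaffold, "", fixed = TRUE)[[1]]
  pos <- as.integer(names(planted))
  if (any(pos < 1 | pos > length(residues)))
    stop("planted positions outside the scaffold")
  residues[pos] <- planted
  loop <- strsplit(EF_CANONICAL_LOOP, "", fixed = TRUE)[[1]]
  loop_pos <- integer(0)
  for (s in ef_loop_starts) {
    idx <- s:(s + 11L)
    if (any(idx > length(residues))) stop("EF loop outside the scaffold")
    residues[idx] <- loop
    loop_pos <- c(loop_pos, idx)
  }
  if (length(ef_loop_starts) > 0)
    residues <- guard_ef_loops(residues, ef_loop_starts,
                               protect = c(pos, loop_pos))
  if (!is.null(domain_layout)) {
    dl <- domain_layout[order(domain_layout$start), , drop = FALSE]
    if (nrow(dl) > 1 && any(dl$start[-1] <= dl$end[-nrow(dl)]))
      stop("domain intervals must be non-overlapping and N-to-C ordered")
  }
  structure(list(name = name, sequence = paste(residues, collapse = ""),
                 planted = planted,
                 protected = sort(unique(c(pos, loop_pos))),
                 ef_loop_starts = ef_loop_starts,
                 domain_layout = domain_layout,
                 nterm_extension = as.integer(nterm_extension),
                 expected_label = expected_label,
                 expected_subtype = expected_subtype,
                 expected_architecture = expected_architecture),
            class = "clade_template")
}

core_triad_layout <- function() {
  data.frame(domain_name = c("FRD", "FAD_binding", "NADPH_binding"),
             start = c(40L, 300L, 430L), end = c(290L, 420L, 560L))
}

#' Default five-clade benchmark templates
#'
#' NOX, preNOX (the green-algal variant profile, which additionally lacks the
#' second TM3 histidine), FRE, YedZ/STEAP1-like and STEAP2-4-like, all on the
#' shared synthetic NOX2-like scaffold with signature-table exemplar residues
#' planted at the seven reference positions.
#'
#' @return Named list of [clade_template()]s.
#' @export
default_clade_templates <- function() {
  tab <- signature_table()
  scaffold <- build_reference_scaffold()
  frd_only <- data.frame(domain_name = "FRD", start = 40L, end = 290L)
  steap24 <- data.frame(domain_name = c("NADP_F420", "FRD"),
                        start = c(2L, 40L), end = c(38L, 290L))
  list(
    "NOX" = clade_template("NOX", tab$exemplars[["NOX"]], scaffold,
                           domain_layout = core_triad_layout(),
                           expected_label = "NOX-group",
                           expected_architecture = "bacterial-long/core-triad"),
    "preNOX" = clade_template("preNOX", tab$exemplars[["preNOX"]], scaffold,
                              domain_layout = core_triad_layout(),
                              expected_label = "preNOX-like",
                              expected_architecture = "bacterial-long/core-triad"),
    "FRE" = clade_template("FRE", tab$exemplars[["FRE"]], scaffold,
                           domain_layout = core_triad_layout(),
                           expected_label = "FRE-group",
                           expected_architecture = "bacterial-long/core-triad"),
    "YedZ-STEAP1" = clade_template("YedZ-STEAP1",
                                   tab$exemplars[["YedZ-STEAP1"]], scaffold,
                                   domain_layout = frd_only,
                                   expected_label = "YedZ/STEAP",
                                   expected_subtype = "YedZ/STEAP1-like",
                                   expected_architecture = "FRD-only"),
    "STEAP2-4" = clade_template("STEAP2-4", tab$exemplars[["STEAP2-4"]],
                                scaffold, domain_layout = steap24,
                                expected_label = "YedZ/STEAP",
                                expected_subtype = "STEAP2-4-like",
                                expected_architecture = "STEAP2-4-like"))
}

substitute_residues <- function(x, sites) {
  for (s in sites) x[s] <- sample(setdiff(AA20, x[s]), 1L)
  x
}

#' Generate one synthetic clade family
#'
#' Each row is the template sequence (plus any N-terminal extension, drawn
#' once per family) with i.i.d. substitutions at rate `epsilon` (to a
#' uniformly chosen different residue; planted sites skipped when
#' `protect_planted`) and deletions written as gaps at rate `indel_rate`
#' (never at planted sites). Fully reproducible from the seed.
#'
#' @param template A [clade_template()].
#' @param config A [generator_config()].
#' @return List with `msa` (a `protein_msa` carrying truth labels) and
#'   `truth` (data frame `seq_id`, `clade`, `planted`).
#' @export
generate_family <- function(template, config) {
  stopifnot(inherits(template, "clade_template"),
            inherits(config, "generator_config"))
  with_seed(config$seed, {
    base <- strsplit(template$sequence, "", fixed = TRUE)[[1]]
    ext <- if (template$nterm_extension > 0)
      sample(AA20, template$nterm_extension, replace = TRUE) else character(0)
    full <- c(ext, base)
    protected <- template$protected + template$nterm_extension
    n_sites <- length(full)
    sub_sites <- if (config$protect_planted)
      setdiff(seq_len(n_sites), protected) else seq_len(n_sites)
    del_sites <- setdiff(seq_len(n_sites), protected)
    safe <- gsub("[^A-Za-z0-9]+", "-", template$name)
    rows <- vapply(seq_len(config$n_per_clade), function(i) {
      x <- full
      muts <- sub_sites[stats::runif(length(sub_sites)) < config$epsilon]
      if (length(muts) > 0) x <- substitute_residues(x, muts)
      dels <- del_sites[stats::runif(length(del_sites)) < config$indel_rate]
      x[dels] <- "-"
      paste(x, collapse = "")
    }, character(1))
    ids <- sprintf("%s_%03d", safe, seq_len(config$n_per_clade))
    msa <- protein_set(id = ids, sequence = rows,
                       description = paste("synthetic", template$name),
                       truth_label = template$name)
    msa <- as_protein_msa(msa)
    planted_str <- paste(names(template$planted), template$planted,
                         sep = "=", collapse = ";")
    truth <- data.frame(seq_id = ids, clade = template$name,
                        planted = planted_str)
    list(msa = msa, truth = truth)
  })
}

#' Generate a multi-clade benchmark on disk
#'
#' Writes one aligned FASTA per clade, a pooled (degapped) FASTA, a truth
#' TSV, a domain-hit TSV consistent with each template's layout, and a
#' manifest JSON recording the configuration. Per-clade generator streams are
#' derived by stable sub-seeding (`seed + clade index`), so adding a clade
#' does not perturb earlier clades.
#'
#' @param config A [generator_config()].
#' @param clades Named list of [clade_template()]s (at least 2).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with file paths and the pooled record count.
#' @export
generate_benchmark <- function(config, clades = default_clade_templates(),
                               outdir) {
  if (length(clades) < 2) stop("at least 2 clades required")
  nm <- vapply(clades, function(tpl) tpl$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate clade names")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  msa_paths <- character(0)
  pooled <- NULL
  truth <- NULL
  hits <- NULL
  for (i in seq_along(clades)) {
    tpl <- clades[[i]]
    sub <- config
    sub$seed <- config$seed + i
    fam <- generate_family(tpl, sub)
    safe <- gsub("[^A-Za-z0-9]+", "-", tpl$name)
    p <- file.path(outdir, paste0(safe, "_msa.fasta"))
    write_fasta(fam$msa, p)
    msa_paths <- c(msa_paths, p)
    degapped <- fam$msa
    degapped$sequence <- gsub("-", "", degapped$sequence, fixed = TRUE)
    pooled <- rbind(pooled, as.data.frame(degapped))
    truth <- rbind(truth, fam$truth)
    if (!is.null(tpl$domain_layout)) {
      shift <- tpl$nterm_extension
      hits <- rbind(hits, do.call(rbind, lapply(fam$truth$seq_id, function(sid)
        data.frame(seq_id = sid, domain_name = tpl$domain_layout$domain_name,
                   start = tpl$domain_layout$start + shift,
                   end = tpl$domain_layout$end + shift,
                   source = "template"))))
    }
  }
  class(pooled) <- c("protein_set", "data.frame")
  pooled_path <- file.path(outdir, "pooled.fasta")
  write_fasta(pooled, pooled_path)
  truth_path <- file.path(outdir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hits_path <- file.path(outdir, "domain_hits.tsv")
  utils::write.table(hits, hits_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest_path <- file.path(outdir, "manifest.json")
  manifest <- list(tool = "frdsig",
                   version = as.character(utils::packageVersion("frdsig")),
                   command = "simulate",
                   config = unclass(config),
                   clades = unname(nm))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(msa_paths = msa_paths, pooled = pooled_path,
                 truth = truth_path, domain_hits = hits_path,
                 manifest = manifest_path, n_sequences = nrow(pooled)))
}
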