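# Desk-scale dataset presets that emulate the two study designs: a densely
# sampled clade of closely related species with several very short internal
# edges ("gammarid-like"), and a sparser, deeper clade with only a few
# ("primate-like"). Edge lengths of the short internal edges mirror those on
# which real bursts have been observed (0.0007-0.004 dS).

#' Gammarid-like preset tree
#'
#' Ten closely related taxa with six internal edges shorter than 0.005 dS
#' (0.0007-0.004, the range on which real bursts have been reported),
#' including consecutive short pairs so that both single-edge and two-edge
#' runs occur. None of the short edges is incident to the root: event
#' placement between the two root edges is not identifiable, so a realistic
#' clade emulation keeps its short edges interior. Branch lengths in dS
#' units.
#'
#' @return A rooted `phylo`.
#' @export
gammarid_tree <- function() {
  parse_newick(paste0(
    "(((t1:0.010,t2:0.010):0.0040,((t3:0.008,t4:0.008):0.0008,",
    "t5:0.012):0.0007):0.020,",
    "((((t6:0.009,t7:0.009):0.0010,t8:0.013):0.0024,t9:0.016):0.0011,",
    "t10:0.018):0.015);"
  ))
}

#' Primate-like preset tree
#'
#' Eleven taxa at larger divergences with exactly three internal edges
#' shorter than 0.005 dS. Branch lengths in dS units.
#'
#' @return A rooted `phylo`.
#' @export
primate_tree <- function() {
  parse_newick(paste0(
    "((((((p1:0.02,p2:0.02):0.0043,p3:0.03):0.010,(p4:0.025,p5:0.025):",
    "0.0030):0.015,(p6:0.04,p7:0.04):0.0020):0.020,(p8:0.05,p9:0.05):",
    "0.030):0.025,(p10:0.06,p11:0.06):0.040);"
  ))
}

#' Build a synthetic dataset from a preset
#'
#' Simulates a complete clade dataset (alignments + tree + truth) and
#' optionally writes it to disk as a self-describing directory: one FASTA
#' per gene under `genes/`, `tree.nwk`, a `manifest.tsv` mapping gene id to
#' alignment path, `truth.tsv` with every simulated event, and `config.json`
#' echoing the generator settings.
#'
#' @param preset `"gammarid"` (10 taxa, 200 genes), `"primate"` (11 taxa,
#'   200 genes) or `"custom"` (supply `tree` and other arguments).
#' @param seed Integer master seed.
#' @param dir Output directory (created if needed); `NULL` keeps the dataset
#'   in memory only.
#' @param n_genes,gene_length,omega,kappa,bursts,gap_rate Overrides passed to
#'   [generator_config()]; defaults come from the preset.
#' @param tree Required for `preset = "custom"`.
#' @return The `codon_simulation`, invisibly when written to disk, with a
#'   `dir` attribute giving the output path if any.
#' @export
make_dataset <- function(preset = c("gammarid", "primate", "custom"), seed,
                         dir = NULL, n_genes = 200L,
                         gene_length = c(150L, 300L), omega = 1, kappa = 2,
                         bursts = NULL, gap_rate = 0, tree = NULL) {
  preset <- match.arg(preset)
  tree <- switch(preset,
    gammarid = gammarid_tree(),
    primate = primate_tree(),
    custom = {
      if (is.null(tree)) stop("custom preset requires a tree", call. = FALSE)
      tree
    }
  )
  config <- generator_config(tree, n_genes = n_genes,
                             gene_length = gene_length, omega = omega,
                             kappa = kappa, bursts = bursts,
                             gap_rate = gap_rate, seed = seed)
  sim <- simulate_alignment(config)
  if (!is.null(dir)) {
    .write_dataset(sim, dir, preset)
    attr(sim, "dir") <- dir
    return(invisible(sim))
  }
  sim
}

.write_dataset <- function(sim, dir, preset) {
  gene_dir <- file.path(dir, "genes")
  dir.create(gene_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(sim$alignments, function(aln) {
    p <- file.path(gene_dir, paste0(aln$gene, ".fa"))
    write_codon_fasta(aln, p)
    p
  }, character(1))
  write_newick(sim$tree, file.path(dir, "tree.nwk"))
  manifest <- data.frame(
    gene = vapply(sim$alignments, `[[`, character(1), "gene"),
    path = file.path("genes", basename(paths)),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  jsonlite::write_json(
    list(preset = preset, n_genes = cfg$n_genes,
         gene_length = cfg$gene_length, omega = cfg$omega,
         kappa = cfg$kappa, gap_rate = cfg$gap_rate, seed = cfg$seed,
         n_taxa = length(sim$tree$tip.label),
         bursts = cfg$bursts),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a dataset directory written by [make_dataset()]
#'
#' @param dir Dataset directory containing `tree.nwk` and `manifest.tsv`.
#' @return A list with `tree` and `alignments`, directly usable by
#'   [scan_bursts()].
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  tree <- read_rooted_tree(file.path(dir, "tree.nwk"))
  alignments <- lapply(seq_len(nrow(manifest)), function(i) {
    read_codon_fasta(file.path(dir, manifest$path[i]),
                     gene = manifest$gene[i])
  })
  names(alignments) <- manifest$gene
  list(tree = tree, alignments = alignments)
}
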