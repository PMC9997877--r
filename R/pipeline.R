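#' Run the full clustering pipeline on a FASTA file
#'
#' Reads sequences, computes composition features and PSM feature vectors,
#' builds the Euclidean distance matrix, grows one tree per linkage
#' method, fuses the cut trees by evidence accumulation, and writes every
#' artifact plus a JSON manifest (configuration echo and MD5 content
#' hashes) into `outdir`. The pipeline has no random component: identical
#' input and configuration produce byte-identical artifacts.
#'
#' Files written: `features.tsv`, `feature_vectors.tsv`,
#' `distances.phylip`, `tree_<method>.nwk` and `clusters_<method>.tsv` per
#' linkage, `coassociation.tsv`, `consensus.nwk`,
#' `consensus_clusters.tsv`, `manifest.json`.
#'
#' @param input_fasta Path to a FASTA file with >= 2 records.
#' @param outdir Output directory (created if missing).
#' @param moment_order,include_dc Passed to [psm_features()].
#' @param methods,k,consensus_method,standardize Passed to
#'   [run_ensemble()].
#' @return The `gene_tree_ensemble`, invisibly.
#' @export
run_pipeline <- function(input_fasta, outdir,
                         moment_order = 3, include_dc = FALSE,
                         methods = linkage_methods(), k = 4,
                         consensus_method = "average",
                         standardize = FALSE) {
  if (k < 1) {
    abort("k must be >= 1", class = "dftree_validation_error")
  }
  seqs <- read_fasta(input_fasta)
  if (nrow(seqs) < 2) {
    abort("pipeline needs at least 2 sequences", class = "dftree_validation_error")
  }
  if (k > nrow(seqs)) {
    abort(paste0("k = ", k, " exceeds the number of sequences (", nrow(seqs), ")"),
          class = "dftree_validation_error")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(outdir, ...)

  feats <- sequence_features(seqs)
  write_features_tsv(feats, path("features.tsv"))
  fv <- psm_features(seqs, moment_order = moment_order, include_dc = include_dc)
  write_feature_vectors_tsv(fv, path("feature_vectors.tsv"))

  ens <- run_ensemble(fv, methods = methods, k = k,
                      consensus_method = consensus_method,
                      standardize = standardize)
  write_distance_matrix(ens$distances, path("distances.phylip"))
  for (m in names(ens$trees)) {
    writeLines(to_newick(ens$trees[[m]]), path(sprintf("tree_%s.nwk", m)))
    lab <- ens$labelings[ens$labelings$clustering == m, c("id", "cluster")]
    write_clusters_tsv(lab, path(sprintf("clusters_%s.tsv", m)))
  }
  write_coassociation_tsv(ens$coassociation, path("coassociation.tsv"))
  writeLines(to_newick(ens$consensus), path("consensus.nwk"))
  write_clusters_tsv(ens$consensus_labels, path("consensus_clusters.tsv"))

  artifacts <- setdiff(list.files(outdir), "manifest.json")
  manifest <- list(
    package = "dftree",
    version = as.character(utils::packageVersion("dftree")),
    config = list(
      input_fasta = input_fasta, outdir = outdir,
      moment_order = moment_order, include_dc = include_dc,
      methods = names(ens$trees), k = k,
      consensus_method = consensus_method, standardize = standardize
    ),
    n_sequences = nrow(seqs),
    artifacts = as.list(tools::md5sum(file.path(outdir, sort(artifacts))))
  )
  names(manifest$artifacts) <- sort(artifacts)
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(ens)
}
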