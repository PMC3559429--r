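#' Simulate a focal transcriptome and diverged reference transcriptomes
#'
#' Draws one random transcript per (gene, isoform) for the focal species,
#' then derives each reference species' copy by independent per-site
#' substitution at that species' divergence rate (uniform over the three
#' alternative bases, no indels). A configurable fraction of genes are
#' "orphans" present in exactly one reference species and absent from the
#' homology table; all other genes are linked across species into one
#' homology cluster per ancestral gene.
#'
#' @param config a [sim_config()].
#' @return a list of class `reference_set` with elements
#'   \describe{
#'     \item{references}{named list of [Biostrings::DNAStringSet], one per
#'       reference species (`sp1`, `sp2`, ...), record ids
#'       `gene|transcript|species`.}
#'     \item{focal}{[Biostrings::DNAStringSet] of the focal ("mole-like")
#'       transcriptome the reads are drawn from.}
#'     \item{gene_model}{data.frame `(species, transcript, gene)` covering
#'       all species including the focal one.}
#'     \item{homology}{data.frame `(cluster, species, gene, provenance)`.}
#'     \item{truth}{list: `orphans` (data.frame gene, species), `entity`
#'       (data.frame gene, entity) mapping each gene to its collapsed row
#'       key — the cluster id, or `species:gene` for orphans.}
#'   }
#' @export
simulate_references <- function(config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "references"), {
    n <- config$n_genes
    genes <- sprintf("g%04d", seq_len(n))
    species <- sprintf("sp%d", seq_len(config$n_species))

    tx_of <- lapply(genes, function(g)
      paste0(g, ".t", seq_len(config$transcripts_per_gene)))
    tx_all <- unlist(tx_of)
    gene_of_tx <- rep(genes, each = config$transcripts_per_gene)

    focal_seqs <- vapply(tx_all, function(.)
      paste(sample(c("A", "C", "G", "T"), config$transcript_len,
                   replace = TRUE), collapse = ""),
      character(1))

    n_orph <- round(config$orphan_fraction * n)
    orphan_genes <- if (n_orph > 0) sort(sample(genes, n_orph)) else character(0)
    orphan_host <- setNames(
      species[(seq_along(orphan_genes) - 1L) %% length(species) + 1L],
      orphan_genes)

    refs <- list()
    gene_model <- data.frame(species = "focal", transcript = tx_all,
                             gene = gene_of_tx, stringsAsFactors = FALSE)
    for (si in seq_along(species)) {
      sp <- species[si]
      keep <- !(gene_of_tx %in% orphan_genes) | orphan_host[gene_of_tx] == sp
      keep[is.na(keep)] <- TRUE
      seqs <- mutate_dna(focal_seqs[keep], config$species_divergence[si])
      names(seqs) <- paste(gene_of_tx[keep], tx_all[keep], sp, sep = "|")
      refs[[sp]] <- Biostrings::DNAStringSet(seqs)
      gene_model <- rbind(gene_model, data.frame(
        species = sp, transcript = tx_all[keep], gene = gene_of_tx[keep],
        stringsAsFactors = FALSE))
    }

    focal <- Biostrings::DNAStringSet(focal_seqs)
    names(focal) <- paste(gene_of_tx, tx_all, "focal", sep = "|")

    clustered <- setdiff(genes, orphan_genes)
    cluster_id <- setNames(sprintf("C%04d", match(clustered, genes)), clustered)
    homology <- data.frame(
      cluster = rep(unname(cluster_id), each = length(species)),
      species = rep(species, times = length(clustered)),
      gene = rep(clustered, each = length(species)),
      provenance = "database",
      stringsAsFactors = FALSE)

    entity <- ifelse(genes %in% orphan_genes,
                     paste0(orphan_host[genes], ":", genes),
                     unname(cluster_id[genes]))

    out <- list(
      references = refs,
      focal = focal,
      gene_model = gene_model,
      homology = homology,
      truth = list(
        orphans = data.frame(gene = orphan_genes,
                             species = unname(orphan_host[orphan_genes]),
                             stringsAsFactors = FALSE),
        entity = data.frame(gene = genes, entity = entity,
                            stringsAsFactors = FALSE)))
    class(out) <- "reference_set"
    out
  })
}

# i.i.d. per-site substitution, uniform over the 3 alternative bases.
mutate_dna <- function(seqs, p) {
  stopifnot(p >= 0, p <= 1)
  if (p > 0.75) stop("substitution probability > 0.75 is degenerate")
  if (p == 0 || length(seqs) == 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    x <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(x)) < p & x %in% bases)
    if (length(hit)) {
      # uniform among the three alternatives: shift by 1..3 in base order
      idx <- match(x[hit], bases)
      x[hit] <- bases[(idx - 1L + sample.int(3L, length(hit),
                                             replace = TRUE)) %% 4L + 1L]
    }
    paste(x, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
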