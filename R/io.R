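# File-format boundary: FASTA / GFF3 / VCF / BED / BedGraph / TSV / JSON.

#' Write a simulated genome to FASTA
#'
#' @param genome An `ems_genome`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a genome FASTA into the package's genome container
#'
#' @param path FASTA path.
#' @param domains Optional domain tibble (chrom, start, end, kind).
#' @return An `ems_genome`.
#' @export
read_genome_fasta <- function(path, domains = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  seqs <- setNames(as.character(x), nm)
  if (is.null(domains)) {
    domains <- tibble(
      chrom = nm, start = 1, end = vapply(seqs, nchar, numeric(1)),
      kind = "euchromatin"
    )
  }
  structure(list(seq = seqs, domains = domains), class = "ems_genome")
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon and CDS features; the `gene_biotype` attribute is
#' `TE` or `non-TE`.
#'
#' @param genes,exons Tibbles from [sim_genes()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, exons, path) {
  feats <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- dplyr::filter(exons, .data$gene_id == g$gene_id)
    tid <- paste0(g$gene_id, ".1")
    feats[[i]] <- dplyr::bind_rows(
      tibble(chrom = g$chrom, start = g$start, end = g$end, strand = g$strand,
             type = "gene", ID = g$gene_id, Parent = NA_character_,
             gene_biotype = g$biotype),
      tibble(chrom = g$chrom, start = g$start, end = g$end, strand = g$strand,
             type = "mRNA", ID = tid, Parent = g$gene_id,
             gene_biotype = g$biotype),
      tibble(chrom = g$chrom, start = ex$start, end = ex$end,
             strand = g$strand, type = "exon",
             ID = paste0(tid, ".exon", seq_len(nrow(ex))), Parent = tid,
             gene_biotype = NA_character_),
      tibble(chrom = g$chrom, start = ex$start, end = ex$end,
             strand = g$strand, type = "CDS",
             ID = paste0(tid, ".cds", seq_len(nrow(ex))), Parent = tid,
             gene_biotype = NA_character_)
    )
  }
  d <- dplyr::bind_rows(feats)
  # CDS phase in transcription order
  d$phase <- NA_integer_
  cds_rows <- which(d$type == "CDS")
  for (tid in unique(d$Parent[cds_rows])) {
    i <- cds_rows[d$Parent[cds_rows] == tid]
    i <- i[order(d$start[i], decreasing = d$strand[i[1]] == "-")]
    cum <- cumsum(c(0, head(d$end[i] - d$start[i] + 1, -1)))
    d$phase[i] <- as.integer((3 - cum %% 3) %% 3)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = d$chrom,
    ranges = IRanges::IRanges(start = d$start, end = d$end),
    strand = d$strand
  )
  S4Vectors::mcols(gr)$type <- d$type
  S4Vectors::mcols(gr)$ID <- d$ID
  S4Vectors::mcols(gr)$Parent <- d$Parent
  S4Vectors::mcols(gr)$gene_biotype <- d$gene_biotype
  S4Vectors::mcols(gr)$phase <- d$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps the longest transcript per gene (matching the codon-usage
#' convention) and returns the package's tabular gene/exon representation.
#'
#' @param path GFF3 path.
#' @return List with `genes` and `exons` tibbles.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  d <- as_tibble(as.data.frame(gr))
  d$Parent <- vapply(d$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  genes <- d %>%
    dplyr::filter(.data$type == "gene") %>%
    dplyr::transmute(
      gene_id = .data$ID, chrom = as.character(.data$seqnames),
      start = .data$start, end = .data$end, strand = as.character(.data$strand),
      biotype = .data$gene_biotype
    )
  tx <- d %>%
    dplyr::filter(.data$type == "mRNA") %>%
    dplyr::transmute(tx_id = .data$ID, gene_id = .data$Parent,
                     tx_len = .data$end - .data$start + 1)
  cds <- d %>%
    dplyr::filter(.data$type == "CDS") %>%
    dplyr::transmute(tx_id = .data$Parent, chrom = as.character(.data$seqnames),
                     start = .data$start, end = .data$end,
                     strand = as.character(.data$strand))
  # longest transcript per gene
  keep_tx <- tx %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::slice_max(.data$tx_len, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup()
  cds <- dplyr::inner_join(cds, keep_tx, by = "tx_id")
  exons <- cds %>%
    dplyr::arrange(.data$gene_id, .data$start) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::mutate(exon_rank = if (dplyr::first(.data$strand) == "+") {
      dplyr::row_number()
    } else {
      dplyr::n() - dplyr::row_number() + 1
    }) %>%
    dplyr::ungroup() %>%
    dplyr::select("gene_id", "exon_rank", "start", "end")
  list(genes = genes, exons = exons)
}

#' Write per-bulk variant tables as VCF 4.2
#'
#' One file per bulk (`<bulk_id>.vcf`), with `DP`/`AD` FORMAT fields and the
#' custom `MQAD` INFO field carrying the count of alt reads with mapping
#' quality >= 20.
#'
#' @param bulk_variants Tibble from [sim_bulk_variants()].
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_bulk_vcfs <- function(bulk_variants, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQAD,Number=1,Type=Integer,Description=\"Alt reads with MQ>=20\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">"
  )
  paths <- character(0)
  for (b in sort(unique(bulk_variants$bulk_id))) {
    d <- bulk_variants %>%
      dplyr::filter(.data$bulk_id == b) %>%
      dplyr::arrange(.data$chrom, .data$pos)
    path <- file.path(dir, paste0(b, ".vcf"))
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tMQAD=%d\tGT:DP:AD\t0/1:%d:%d,%d",
      d$chrom, d$pos, d$ref, d$alt, d$alt_reads_mq20,
      d$total_reads, d$total_reads - d$alt_reads, d$alt_reads
    )
    writeLines(c(
      header,
      paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", b),
      body
    ), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read per-bulk VCFs back into a bulk-variant table
#'
#' @param paths VCF file paths (one per bulk; sample name = bulk id).
#' @param mq_field INFO field holding the MQ>=20 alt-read count; when absent
#'   from a file, `alt_reads` is used as a fallback.
#' @return Tibble with the [sim_bulk_variants()] columns (minus `origin`).
#' @export
read_bulk_vcfs <- function(paths, mq_field = "MQAD") {
  purrr::map_dfr(paths, function(p) {
    v <- vcfR::read.vcfR(p, verbose = FALSE)
    fixm <- v@fix # matrix even for a single record
    fix <- tibble(
      CHROM = fixm[, "CHROM"], POS = fixm[, "POS"],
      REF = fixm[, "REF"], ALT = fixm[, "ALT"]
    )
    bulk <- colnames(v@gt)[2]
    dp <- as.integer(vcfR::extract.gt(v, "DP")[, 1])
    ad <- vcfR::extract.gt(v, "AD")[, 1]
    ad_alt <- as.integer(vapply(strsplit(ad, ",", fixed = TRUE), `[`, character(1), 2))
    mq <- suppressWarnings(as.integer(vcfR::extract.info(v, mq_field)))
    if (all(is.na(mq))) mq <- ad_alt
    tibble(
      bulk_id = bulk, chrom = fix$CHROM, pos = as.numeric(fix$POS),
      ref = fix$REF, alt = fix$ALT, total_reads = dp, alt_reads = ad_alt,
      alt_reads_mq20 = mq
    )
  }) %>% dplyr::arrange(.data$bulk_id, .data$chrom, .data$pos)
}

#' Write/read interval tracks (BED3 and BedGraph)
#'
#' Coordinates are converted between the package's 1-based inclusive
#' intervals and BED's 0-based half-open convention by rtracklayer.
#'
#' @param intervals Tibble (chrom, start, end\[, value\]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed3 <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    intervals$chrom, IRanges::IRanges(intervals$start, intervals$end)
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_bed3
#' @export
read_bed3 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr)
  )
}

#' @rdname write_bed3
#' @export
write_bedgraph <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    intervals$chrom, IRanges::IRanges(intervals$start, intervals$end),
    score = intervals$value
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bed3
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    value = gr$score
  )
}

#' Write / read the simulator ground-truth manifest (JSON)
#'
#' Round-trips losslessly: `read_truth_manifest(write_truth_manifest(x, p))`
#' reproduces the truth tables exactly.
#'
#' @param truth The `truth` element of an `ems_simulation`.
#' @param path JSON path.
#' @return `path` / truth list.
#' @export
write_truth_manifest <- function(truth, path) {
  jsonlite::write_json(
    lapply(truth, function(d) as.data.frame(d)),
    path, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname write_truth_manifest
#' @export
read_truth_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, function(d) {
    d <- as_tibble(d)
    if ("pos" %in% names(d)) d$pos <- as.integer(d$pos)
    d
  })
}

#' Write simulation inputs to a directory
#'
#' Materialises the full simulated study as standard files: FASTA genome,
#' GFF3 genes, per-bulk VCFs, DH BED3, one BedGraph per signal experiment
#' plus a track manifest TSV, FPKM TSV, panel TSV, and the ground-truth
#' manifest JSON.
#'
#' @param sim An `ems_simulation`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  readr::write_tsv(sim$genome$domains, file.path(dir, "domains.tsv"))
  write_genes_gff3(sim$genes, sim$exons, file.path(dir, "genes.gff3"))
  write_bulk_vcfs(sim$bulk_variants, file.path(dir, "vcf"))
  write_bed3(sim$tracks$dh, file.path(dir, "dh_sites.bed"))
  tdir <- file.path(dir, "tracks")
  dir.create(tdir, showWarnings = FALSE)
  manifest <- sim$tracks$signals %>%
    dplyr::distinct(.data$modification, .data$experiment) %>%
    dplyr::mutate(file = file.path("tracks", paste0(.data$experiment, ".bedgraph")))
  for (i in seq_len(nrow(manifest))) {
    d <- dplyr::filter(sim$tracks$signals,
                       .data$experiment == manifest$experiment[i])
    write_bedgraph(d, file.path(dir, manifest$file[i]))
  }
  readr::write_tsv(manifest, file.path(dir, "track_manifest.tsv"))
  readr::write_tsv(sim$tracks$fpkm, file.path(dir, "fpkm.tsv"))
  readr::write_tsv(panel_site_stats(sim$panel), file.path(dir, "panel_sites.tsv"))
  write_truth_manifest(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
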