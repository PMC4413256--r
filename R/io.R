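#' Write simulated data as standard-format fixture files
#'
#' Serializes a simulated dataset to a directory using the field's standard
#' plain-text formats: genotypes as a minimal VCF 4.2 (haploid-coded
#' homozygous GTs) plus a tabular 0/1 matrix, accession metadata as TSV,
#' annotations as GFF3 (1-based closed) and BED6 (0-based half-open),
#' methylomes as per-sample cytosine-report TSVs, and expression as TSV.
#' [read_fixtures()] inverts the operation; write-then-read is the
#' identity on genotype calls, methylation counts and annotation features.
#'
#' @param genotypes A `geno_table`.
#' @param annot An `annot_set`.
#' @param counts Methylation counts tibble (from [simulate_methylomes()]).
#' @param dir Output directory (created if absent).
#' @param expression Optional expression tibble.
#' @return Invisibly, the vector of files written.
#' @export
write_fixtures <- function(genotypes, annot, counts, dir, expression = NULL) {
  stopf(inherits(genotypes, "geno_table"), "genotypes must be a geno_table")
  stopf(nrow(genotypes$calls) > 0, "empty accession list: nothing to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  vcf <- file.path(dir, "genotypes.vcf")
  write_genotypes_vcf(genotypes, vcf)
  files <- c(files, vcf)

  gt_tsv <- file.path(dir, "genotypes.tsv")
  readr::write_tsv(tibble::as_tibble(genotypes$calls, rownames = "accession"),
                   gt_tsv)
  files <- c(files, gt_tsv)

  meta <- file.path(dir, "accessions.tsv")
  readr::write_tsv(genotypes$accessions, meta)
  files <- c(files, meta)

  if (!is.null(annot)) {
    gff <- file.path(dir, "annotations.gff3")
    bed <- file.path(dir, "annotations.bed")
    gr <- features_to_granges(annot)
    rtracklayer::export(gr, gff, format = "gff3")
    rtracklayer::export(gr, bed, format = "bed")
    files <- c(files, gff, bed)
  }

  if (!is.null(counts)) {
    mdir <- file.path(dir, "methylomes")
    dir.create(mdir, showWarnings = FALSE)
    groups <- dplyr::group_split(dplyr::group_by(counts, .data$accession, .data$env))
    for (g in groups) {
      f <- file.path(mdir, sprintf("%s_%s.tsv", g$accession[1], g$env[1]))
      readr::write_tsv(g[, c("chrom", "pos", "strand", "context", "meth", "total")], f)
      files <- c(files, f)
    }
  }

  if (!is.null(expression)) {
    f <- file.path(dir, "expression.tsv")
    readr::write_tsv(expression, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' @rdname write_fixtures
#' @param check Validate invariants (counts within depth, positions in
#'   bounds) while reading.
#' @return `read_fixtures()` returns a list with `genotypes`, `annot`
#'   (features tibble), `counts` and, when present, `expression`.
#' @export
read_fixtures <- function(dir, check = TRUE) {
  stopf(dir.exists(dir), "fixture directory not found: %s", dir)
  geno <- read_genotypes_vcf(file.path(dir, "genotypes.vcf"),
                             file.path(dir, "accessions.tsv"))
  feats <- NULL
  gff <- file.path(dir, "annotations.gff3")
  if (file.exists(gff)) feats <- read_features_gff3(gff)
  counts <- NULL
  mdir <- file.path(dir, "methylomes")
  if (dir.exists(mdir)) {
    fs <- list.files(mdir, pattern = "\\.tsv$", full.names = TRUE)
    counts <- purrr::map_dfr(fs, function(f) {
      key <- strsplit(sub("\\.tsv$", "", basename(f)), "_")[[1]]
      tb <- readr::read_tsv(f, show_col_types = FALSE,
                            col_types = readr::cols(chrom = "c", strand = "c",
                                                    context = "c"))
      if (check) stopf(all(tb$meth <= tb$total),
                       "meth > total in %s", basename(f))
      dplyr::mutate(tb, accession = key[1], env = key[2], .before = 1)
    })
    counts <- dplyr::mutate(counts, pos = as.integer(.data$pos),
                            meth = as.integer(.data$meth),
                            total = as.integer(.data$total))
  }
  expr <- NULL
  ef <- file.path(dir, "expression.tsv")
  if (file.exists(ef)) expr <- readr::read_tsv(ef, show_col_types = FALSE)
  list(genotypes = geno, annot = feats, counts = counts, expression = expr)
}

write_genotypes_vcf <- function(genotypes, path) {
  snps <- genotypes$snps
  calls <- genotypes$calls
  info <- rep(".", nrow(snps))
  ml <- match(genotypes$major_locus, snps$snp_id)
  info[ml] <- paste0("MAJOR=", names(genotypes$major_locus))
  gt <- t(calls)                                     # snps x accessions
  body <- paste(snps$chrom, snps$pos, snps$snp_id, "A", "T", ".", "PASS",
                info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", names(genotypes$chrom_lengths),
                     ",length=", genotypes$chrom_lengths, ">"),
              "##INFO=<ID=MAJOR,Number=1,Type=String,Description=\"Major-locus pair member\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(calls)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

read_genotypes_vcf <- function(path, meta_path = NULL) {
  stopf(file.exists(path), "VCF not found: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  contig <- vcf@meta[grepl("^##contig", vcf@meta)]
  cl <- setNames(as.numeric(sub(".*length=([0-9]+)>.*", "\\1", contig)),
                 sub(".*ID=([^,]+),.*", "\\1", contig))
  snps <- tibble::tibble(snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]))
  gt <- vcfR::extract.gt(vcf)                      # snps x accessions
  acc <- colnames(gt)
  calls <- t(matrix(as.integer(gt), nrow(gt), ncol(gt)))
  dimnames(calls) <- list(acc, snps$snp_id)
  info <- fix[, "INFO"]
  major <- grep("MAJOR=", info)
  major_locus <- setNames(snps$snp_id[major],
                          sub(".*MAJOR=([ab]).*", "\\1", info[major]))
  accessions <- tibble::tibble(accession = acc)
  if (!is.null(meta_path) && file.exists(meta_path)) {
    meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
    accessions <- meta[match(acc, meta$accession), ]
  }
  structure(list(calls = calls, snps = snps, accessions = accessions,
                 major_locus = major_locus[c("a", "b")],
                 chrom_lengths = cl, fst_target = NA_real_),
            class = "geno_table")
}

features_to_granges <- function(annot) {
  f <- annot$features
  gr <- GenomicRanges::GRanges(
    seqnames = f$chrom,
    ranges = IRanges::IRanges(start = f$start, end = f$end),
    strand = f$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = ifelse(f$type == "gene", "gene", "transposable_element"),
    ID = f$feature_id, Name = f$feature_id,
    family = f$family, superfamily = f$superfamily,
    variable = as.character(f$variable),
    variable_direction = f$variable_direction,
    gbm_gene = as.character(f$gbm_gene))
  gr
}

read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  tibble::tibble(
    feature_id = as.character(mc$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = ifelse(as.character(mc$type) == "gene", "gene", "TE"),
    family = as.character(mc$family),
    superfamily = as.character(mc$superfamily),
    variable = as.logical(mc$variable),
    variable_direction = as.character(mc$variable_direction),
    gbm_gene = as.logical(mc$gbm_gene))
}
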