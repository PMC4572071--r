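# Readers and writers binding the pipeline to standard formats.
# VCF parsing goes through vcfR and GTF/BED parsing through rtracklayer;
# the writers emit plain text directly (uncompressed VCF 4.2 with GT:DP,
# GTF2 CDS features, BED via rtracklayer, PLINK-style .hom).

.GT_STRINGS <- c("0/0", "0/1", "1/1")

#' Write a call set as an uncompressed multi-sample VCF 4.2
#'
#' Emits `GT:DP` per sample; genotypes 0/1/2/NA become `0/0`, `0/1`,
#' `1/1`, `./.`.
#'
#' @param callset A [hlof_callset()].
#' @param path Output path.
#' @param contigs Optional data.frame `contig`, `length` for header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(callset, path, contigs = NULL) {
  v <- callset$variants
  hdr <- c("##fileformat=VCFv4.2",
           "##source=hlofscan",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", contigs$contig,
                     as.integer(contigs$length)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", callset$samples$sample_id),
                 collapse = "\t"))
  g <- callset$geno
  gt <- matrix(.GT_STRINGS[g + 1L], nrow(g), ncol(g))
  gt[is.na(g)] <- "./."
  cells <- matrix(paste0(gt, ":", callset$depth), nrow(g), ncol(g))
  body <- do.call(paste, c(list(v$contig, v$pos, v$key, v$ref, v$alt,
                                ".", "PASS", ".", "GT:DP"),
                           as.data.frame(cells), list(sep = "\t")))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into a call set
#'
#' Sites are expected biallelic (run [decompose_multiallelic()] upstream
#' otherwise); `GT` and `DP` FORMAT fields are required.
#'
#' @param path VCF path (plain or bgzipped).
#' @param samples data.frame `sample_id`, `population`; must cover the
#'   VCF sample columns.
#' @return A [hlof_callset()].
#' @export
read_vcf <- function(path, samples) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  variants <- data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, "GT")
  dp <- vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt))
  for (code in 0:2) geno[gt == .GT_STRINGS[code + 1L]] <- code
  geno[gt %in% c("0|0")] <- 0L; geno[gt %in% c("0|1", "1|0")] <- 1L
  geno[gt %in% c("1|1")] <- 2L
  samples <- samples[match(colnames(gt), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) stop("VCF samples missing from sample table")
  hlof_callset(variants, geno, matrix(as.integer(dp), nrow(dp), ncol(dp)),
               samples)
}

# raw per-record representation used by decompose_multiallelic()
records_from_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, "GT")
  lapply(seq_len(nrow(fix)), function(i) list(
    contig = fix$CHROM[i], pos = as.integer(fix$POS[i]), ref = fix$REF[i],
    alt = strsplit(fix$ALT[i], ",")[[1]], gt = unname(gt[i, ])))
}

#' Write transcript models as GTF CDS features plus a CDS FASTA
#'
#' @param transcripts list of [transcript_model()]s.
#' @param gtf_path,fasta_path Output paths.
#' @return `gtf_path`, invisibly.
#' @export
write_transcripts <- function(transcripts, gtf_path, fasta_path) {
  lines <- unlist(lapply(transcripts, function(tx) {
    ex <- tx$exons
    ord <- if (tx$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    lens <- ex$end - ex$start + 1
    cum <- cumsum(c(0, lens[ord]))[seq_len(nrow(ex))]
    frame <- (3 - cum %% 3) %% 3
    sprintf("%s\thlofscan\tCDS\t%d\t%d\t.\t%s\t%d\tgene_id \"%s\"; transcript_id \"%s\";",
            tx$contig, ex$start[ord], ex$end[ord], tx$strand, frame,
            tx$gene_id, tx$transcript_id)
  }))
  writeLines(lines, gtf_path)
  seqs <- Biostrings::DNAStringSet(
    setNames(vapply(transcripts, `[[`, character(1), "cds_seq"),
             vapply(transcripts, `[[`, character(1), "transcript_id")))
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(gtf_path)
}

#' Read transcript models from a GTF and CDS FASTA
#' @param gtf_path GTF with CDS features carrying `gene_id`/`transcript_id`.
#' @param fasta_path FASTA of spliced CDS sequences named by transcript id.
#' @return list of [transcript_model()]s.
#' @export
read_transcripts <- function(gtf_path, fasta_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "CDS"]
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- unique(gr$transcript_id)
  lapply(ids, function(id) {
    sub <- gr[gr$transcript_id == id]
    transcript_model(
      gene_id = unique(sub$gene_id), transcript_id = id,
      contig = as.character(GenomicRanges::seqnames(sub))[1],
      strand = as.character(BiocGenerics::strand(sub))[1],
      exons = data.frame(start = GenomicRanges::start(sub),
                         end = GenomicRanges::end(sub)),
      cds_seq = as.character(seqs[[id]]))
  })
}

#' Write / read genomic interval tracks as BED
#'
#' Coordinates are converted between the package's 1-based inclusive
#' convention and BED's 0-based half-open convention by rtracklayer.
#'
#' @param gr A GRanges (optionally with a `score` column).
#' @param path BED path.
#' @return `path` (writer) or a GRanges (reader).
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' Write a full synthetic study bundle to a directory
#'
#' Standard formats throughout: VCF (genotypes and depths), GTF + FASTA
#' (transcript models), BED (alignability, blacklist and capture tracks),
#' PLINK-style .hom (ROHs) and TSV (samples, phenotypes, truth table,
#' primate alleles, known catalogue, scores, annotations).
#'
#' @param study An `hlof_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_vcf(study$callset, fp("genotypes.vcf"), study$contigs)
  write_transcripts(study$transcripts, fp("transcripts.gtf"),
                    fp("transcripts_cds.fa"))
  write_bed(study$tracks$alignability[[1]], fp("alignability_1.bed"))
  write_bed(study$tracks$alignability[[2]], fp("alignability_2.bed"))
  write_bed(study$tracks$blacklist, fp("blacklist.bed"))
  write_bed(study$tracks$kit_a, fp("capture_kit_a.bed"))
  write_bed(study$tracks$kit_b, fp("capture_kit_b.bed"))
  write_roh(study$roh, fp("roh.hom"))
  tsv <- function(x, name) data.table::fwrite(x, fp(name), sep = "\t",
                                              na = "NA", quote = FALSE)
  tsv(study$samples, "samples.tsv")
  tsv(study$contigs, "contigs.tsv")
  tsv(study$truth, "truth.tsv")
  tsv(study$primates, "primates.tsv")
  tsv(study$tables$known_catalogue, "known_catalogue.tsv")
  tsv(study$tables$cscores, "cscores.tsv")
  tsv(study$tables$go_annotations, "go_annotations.tsv")
  tsv(study$tables$paralogues, "paralogues.tsv")
  expr <- data.frame(gene = rownames(study$tables$expression),
                     study$tables$expression, check.names = FALSE)
  tsv(expr, "expression.tsv")
  phen <- data.frame(sample_id = rownames(study$phenotypes),
                     study$phenotypes, check.names = FALSE)
  tsv(phen, "phenotypes.tsv")
  invisible(dir)
}

#' Read a study bundle written by [write_study()]
#'
#' @param dir Study directory.
#' @return list with `samples`, `contigs`, `callset`, `transcripts`,
#'   `tracks`, `roh`, `phenotypes`, `truth`, `primates`, `tables`.
#' @export
read_study <- function(dir) {
  fp <- function(...) file.path(dir, ...)
  tsv <- function(name) as.data.frame(data.table::fread(fp(name), sep = "\t"))
  samples <- tsv("samples.tsv")
  callset <- read_vcf(fp("genotypes.vcf"), samples)
  phen <- tsv("phenotypes.tsv")
  phenotypes <- as.matrix(phen[, -1, drop = FALSE])
  rownames(phenotypes) <- phen$sample_id
  expr_df <- tsv("expression.tsv")
  expression <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expression) <- expr_df$gene
  list(
    samples = samples, contigs = tsv("contigs.tsv"), callset = callset,
    transcripts = read_transcripts(fp("transcripts.gtf"),
                                   fp("transcripts_cds.fa")),
    tracks = list(
      alignability = list(read_bed(fp("alignability_1.bed")),
                          read_bed(fp("alignability_2.bed"))),
      blacklist = read_bed(fp("blacklist.bed")),
      kit_a = read_bed(fp("capture_kit_a.bed")),
      kit_b = read_bed(fp("capture_kit_b.bed"))),
    roh = read_roh(fp("roh.hom")),
    phenotypes = phenotypes,
    truth = tsv("truth.tsv"),
    primates = tsv("primates.tsv"),
    tables = list(
      known_catalogue = tsv("known_catalogue.tsv"),
      cscores = tsv("cscores.tsv"),
      go_annotations = tsv("go_annotations.tsv"),
      paralogues = tsv("paralogues.tsv"),
      expression = expression))
}
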