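#' Transcript models
#'
#' A transcript model holds the gene/transcript identity, strand and the
#' ordered CDS segments (1-based, inclusive, genomic coordinates) together
#' with the spliced coding sequence in sense-strand orientation. The total
#' CDS length must be divisible by three; the protein length excludes the
#' terminal stop codon.
#'
#' @param gene_id,transcript_id Identifiers.
#' @param contig Contig name.
#' @param strand "+" or "-".
#' @param exons data.frame with columns `start`, `end` (CDS segments,
#'   non-overlapping; any order, stored sorted by start).
#' @param cds_seq Spliced coding sequence (sense strand), length equal to
#'   the summed segment lengths.
#' @return A `transcript_model` list.
#' @export
transcript_model <- function(gene_id, transcript_id, contig, strand, exons, cds_seq) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  stopifnot(all(exons$end >= exons$start))
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("CDS segments overlap in transcript ", transcript_id)
  len <- sum(exons$end - exons$start + 1)
  if (len %% 3 != 0)
    stop("CDS length not divisible by 3 in transcript ", transcript_id)
  if (nchar(cds_seq) != len)
    stop("cds_seq length does not match segments in transcript ", transcript_id)
  structure(list(
    gene_id = gene_id, transcript_id = transcript_id, contig = contig,
    strand = strand, exons = exons, cds_seq = cds_seq,
    cds_len = len, protein_len = len / 3 - 1
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s (%s) %s:%s %d segment(s), %d codons>\n",
              x$transcript_id, x$gene_id, x$contig, x$strand,
              nrow(x$exons), x$protein_len))
  invisible(x)
}

# cumulative spliced length before each segment (ascending genomic order)
.tx_cum_before <- function(tx) {
  lens <- tx$exons$end - tx$exons$start + 1
  cumsum(c(0, lens))[seq_len(nrow(tx$exons))]
}

#' Map a genomic position to a 1-based index in the spliced CDS
#'
#' Strand-aware: on the minus strand index 1 is the highest genomic CDS
#' coordinate. Returns `NA` for positions outside every CDS segment.
#'
#' @param tx A [transcript_model()].
#' @param pos Genomic position (1-based).
#' @return Integer CDS index or `NA`.
#' @export
genomic_to_cds <- function(tx, pos) {
  hit <- which(pos >= tx$exons$start & pos <= tx$exons$end)
  if (length(hit) == 0) return(NA_integer_)
  cum <- .tx_cum_before(tx)
  idx_plus <- cum[hit] + (pos - tx$exons$start[hit]) + 1L
  if (tx$strand == "+") as.integer(idx_plus)
  else as.integer(tx$cds_len - idx_plus + 1L)
}

#' Map a 1-based spliced-CDS index back to its genomic position
#' @param tx A [transcript_model()].
#' @param idx CDS index in 1..cds_len.
#' @return Genomic position.
#' @export
cds_to_genomic <- function(tx, idx) {
  stopifnot(idx >= 1, idx <= tx$cds_len)
  idx_plus <- if (tx$strand == "+") idx else tx$cds_len - idx + 1L
  cum <- .tx_cum_before(tx)
  seg <- findInterval(idx_plus - 1L, cum)
  as.integer(tx$exons$start[seg] + (idx_plus - cum[seg]) - 1L)
}

.comp <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

.revcomp <- function(x) {
  vapply(x, function(s) .comp(paste(rev(strsplit(s, "")[[1]]), collapse = "")),
         character(1), USE.NAMES = FALSE)
}

# sense-strand base of the CDS at a given CDS index
.cds_base <- function(tx, idx) substr(tx$cds_seq, idx, idx)

# genomic reference base at a genomic position inside the CDS
tx_ref_base <- function(tx, pos) {
  idx <- genomic_to_cds(tx, pos)
  if (is.na(idx)) return(NA_character_)
  b <- .cds_base(tx, idx)
  if (tx$strand == "+") b else .comp(b)
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.codon_of <- function(idx) as.integer((idx - 1L) %/% 3L + 1L)

# the three CDS indices of a codon
.codon_indices <- function(codon) (codon - 1L) * 3L + 1:3

.translate_codon <- function(codon) {
  Biostrings::GENETIC_CODE[[codon]]
}
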