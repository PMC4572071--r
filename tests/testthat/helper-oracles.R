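# Independent oracles used across the suite. Each is written from the
# definition of the quantity it checks, not from the implementation path.

# --- Levene-Haldane heterozygote distribution by dynamic enumeration ----
# Processes individuals one at a time, counting ordered allele
# arrangements: a heterozygote contributes two orderings. Independent of
# the closed-form pmf used by hwe_excess_test().
dp_het_distribution <- function(n, n_alt) {
  ways <- matrix(0, n_alt + 1, n_alt + 2)  # [alt used + 1, hets + 1]
  ways[1, 1] <- 1
  for (ind in seq_len(n)) {
    nxt <- matrix(0, n_alt + 1, n_alt + 2)
    for (a in 0:n_alt) {
      for (h in 0:n_alt) {
        w <- ways[a + 1, h + 1]
        if (w == 0) next
        nxt[a + 1, h + 1] <- nxt[a + 1, h + 1] + w            # hom ref
        if (a + 1 <= n_alt)
          nxt[a + 2, h + 2] <- nxt[a + 2, h + 2] + 2 * w      # het (2 orders)
        if (a + 2 <= n_alt)
          nxt[a + 3, h + 1] <- nxt[a + 3, h + 1] + w          # hom alt
      }
    }
    ways <- nxt
  }
  counts <- ways[n_alt + 1, seq_len(n_alt + 1)]
  hets <- which(counts > 0) - 1L
  data.frame(het = hets, p = counts[hets + 1] / sum(counts))
}

# one-sided tail for homozygote excess from the enumeration distribution
oracle_hwe_excess_p <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2 * n_hom_alt + n_het
  if (n_alt == 0 || n_alt == 2 * n) return(1)
  dist <- dp_het_distribution(n, min(n_alt, 2 * n - n_alt))
  sum(dist$p[dist$het <= n_het])
}

# brute force over every ordered allele sequence, for validating the DP
brute_het_distribution <- function(n, n_alt) {
  slots <- 2 * n
  counts <- numeric(n_alt + 1)
  for (mask in 0:(2^slots - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(slots)]
    if (sum(bits) != n_alt) next
    pairs <- matrix(bits, ncol = 2, byrow = TRUE)
    h <- sum(rowSums(pairs) == 1)
    counts[h + 1] <- counts[h + 1] + 1
  }
  hets <- which(counts > 0) - 1L
  data.frame(het = hets, p = counts[hets + 1] / sum(counts))
}

# --- consequence oracle: full mutated-CDS retranslation -----------------
# Walks the exons to build its own genomic-position <-> CDS map, applies
# the edit to the spliced sequence, and labels the variant from the
# translation of the mutated CDS.
oracle_consequence <- function(variant, tx) {
  pos_map <- unlist(lapply(seq_len(nrow(tx$exons)), function(j)
    seq(tx$exons$start[j], tx$exons$end[j])))
  if (tx$strand == "-") pos_map <- rev(pos_map)
  # sense-strand base by CDS index; index of a genomic position
  idx_of <- function(p) match(p, pos_map)
  vt <- hlofscan::variant_type(variant$ref, variant$alt)
  cds <- strsplit(tx$cds_seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  translate_str <- function(x) {
    x <- x[seq_len(3 * (length(x) %/% 3))]
    as.character(Biostrings::translate(
      Biostrings::DNAString(paste(x, collapse = "")),
      if.fuzzy.codon = "X"))
  }
  if (vt == "SNV") {
    i <- idx_of(variant$pos)
    if (is.na(i)) return("non_coding")
    alt_sense <- if (tx$strand == "+") variant$alt else comp[[variant$alt]]
    mut <- cds; mut[i] <- alt_sense
    aa_ref <- strsplit(translate_str(cds), "")[[1]]
    aa_mut <- strsplit(translate_str(mut), "")[[1]]
    ci <- (i - 1) %/% 3 + 1
    if (aa_mut[ci] == "*" && aa_ref[ci] != "*") return("stop_gain")
    if (identical(aa_ref, aa_mut)) return("synonymous")
    return("missense")
  }
  if (vt == "deletion") {
    span <- seq(variant$pos + 1, variant$pos + nchar(variant$ref) - 1)
    idx <- idx_of(span); idx <- idx[!is.na(idx)]
    if (length(idx) == 0) return("non_coding")
    return(if (length(idx) %% 3 != 0) "frameshift" else "inframe")
  }
  # insertion between pos and pos + 1: inside the CDS only when both
  # flanking bases are coding
  if (is.na(idx_of(variant$pos)) || is.na(idx_of(variant$pos + 1)))
    return("non_coding")
  len <- nchar(variant$alt) - nchar(variant$ref)
  if (len %% 3 != 0) "frameshift" else "inframe"
}

# --- misc small oracles -------------------------------------------------

# binomial tails by direct summation of the pmf
oracle_binom_upper <- function(k, n, p) sum(dbinom(k:n, n, p))
oracle_binom_lower <- function(k, n, p) sum(dbinom(0:k, n, p))

# hypergeometric upper tail by direct summation
oracle_hyper_upper <- function(N, B, n, b) {
  ks <- b:min(B, n)
  sum(choose(B, ks) * choose(N - B, n - ks)) / choose(N, n)
}

# two-sided Fisher P by hypergeometric point-probability enumeration
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Benjamini-Hochberg by the step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# exact rank-sum null distribution by enumerating group assignments
oracle_ranksum_p <- function(x, y) {
  nx <- length(x); vals <- c(x, y)
  r <- rank(vals)
  obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(vals), nx)
  stats <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}
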