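# Independent oracles used by the tests.
#
# The derivative-chromosome oracle works at sequence level: a haplotype is
# a vector of signed 1-based reference positions in traversal order
# (negative = reverse orientation).  This path shares no code with the
# segment-arithmetic implementation.

seqNew <- function(L) seq_len(L)

.seqRun <- function(v, iv) {
  idx <- which(v > 0 & v > iv[1L] & v <= iv[2L])
  stopifnot(length(idx) == iv[2L] - iv[1L], all(diff(idx) == 1))
  idx
}

seqDelete <- function(v, iv) v[-.seqRun(v, iv)]

seqTandem <- function(v, iv) {
  idx <- .seqRun(v, iv)
  append(v, v[idx], after = max(idx))
}

seqInvert <- function(v, iv) {
  idx <- .seqRun(v, iv)
  v[idx] <- -rev(v[idx])
  v
}

seqTemplated <- function(v, p) {
  tpl <- (p$templateStart + 1):(p$templateStart + p$templateLen)
  copy <- if (p$inverted) -rev(tpl) else tpl
  site <- .seqRun(v, c(p$insertionPos, p$insertionPos + p$siteDeletionLen))
  append(v[-site], copy, after = min(site) - 1L)
}

seqBfb1 <- function(v, b) c(v[seq_len(b)], -rev(v[seq_len(b)]))

# junctions implied by non-contiguous neighbours in the position vector
seqJunctions <- function(v, chrom = "chr1") {
  brk <- which(v[-1L] != v[-length(v)] + 1)
  if (!length(brk)) return(JunctionSet())
  left <- v[brk]; right <- v[brk + 1L]
  JunctionSet(data.frame(
    chromA = chrom,
    posA = abs(left) - 1,
    sideA = ifelse(left > 0, "R", "L"),
    chromB = chrom,
    posB = abs(right) - 1,
    sideB = ifelse(right > 0, "L", "R"),
    insertLen = 0, stringsAsFactors = FALSE))
}

# per-base copy number implied by the position vector
seqCN <- function(v, L, baseline = 2L) {
  tabulate(abs(v), nbins = L) + baseline - 1L
}

# expand a CNProfile to a per-base vector
cnPerBase <- function(cn) {
  seg <- segments(cn)
  rep(seg$cn, seg$end - seg$start)
}

# exact two-sided Wilcoxon rank-sum p by full enumeration over all
# assignments of the pooled ranks (distinct values assumed)
wilcoxEnumP <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(a)
  ranks <- rank(pooled)
  obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all <- utils::combn(length(pooled), n1)
  W <- apply(all, 2L, function(idx) sum(ranks[idx])) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(W <= obs), mean(W >= obs)))
}

# Monte-Carlo meiosis oracle: simulate gamete pairs directly and score
# phenotypes through the genotype table, independent of expectedProgeny()
mcProgeny <- function(cross, r, n, seed) {
  set.seed(seed)
  haps <- c("normal", "balancer", "rec1", "rec2")
  pg <- c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2)
  g1 <- sample(haps, n, replace = TRUE, prob = pg)
  g2 <- sample(haps, n, replace = TRUE, prob = pg)
  key <- ifelse(g1 <= g2, paste(g1, g2, sep = "/"),
                paste(g2, g1, sep = "/"))
  geno <- genotypeTable(cross)
  lut <- setNames(geno$phenotype, geno$genotype)
  # unordered genotype names in the table follow haplotype declaration
  # order, not alphabetical order; remap
  lut2 <- lut
  names(lut2) <- vapply(strsplit(names(lut), "/"), function(x)
    paste(sort(x), collapse = "/"), character(1))
  table(factor(lut2[key], levels = unique(geno$phenotype)))
}
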