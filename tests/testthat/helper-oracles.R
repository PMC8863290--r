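# Shared test helpers: tiny panels with known haplotype counts, an
# independently coded tier oracle, and exact-size enumeration for the
# binomial imbalance caller.

# Panel with the given counts of haplotypes AB, Ab, aB, ab over two variants
# (allele 1 = A/B). Counts are padded to an even chromosome total by
# duplicating the panel, which leaves all LD statistics unchanged.
counts_panel <- function(n_AB, n_Ab, n_aB, n_ab) {
  h <- rbind(
    matrix(rep(c(1, 1), n_AB), ncol = 2, byrow = TRUE),
    matrix(rep(c(1, 0), n_Ab), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 1), n_aB), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 0), n_ab), ncol = 2, byrow = TRUE)
  )
  if (nrow(h) %% 2L == 1L) h <- rbind(h, h)
  haplotype_panel(h, data.frame(variant_id = c("va", "vb"),
                                chrom = "chr1", pos = c(100L, 200L),
                                ref = "A", alt = "G"))
}

# Independent brute-force tier rule, written directly from the prose
# definition of the tier classes (not from the package implementation):
# no evidence -> 3; evidence only confirms annotated genes -> 1; new genes
# while supporting all annotated -> 2A, some -> 2B, none -> 2C.
oracle_tier <- function(g, q) {
  g <- unique(g); q <- unique(q)
  if (length(q) == 0) return("3")
  introduces_new <- length(setdiff(q, g)) > 0
  if (!introduces_new) return("1")
  supported <- intersect(g, q)
  if (length(g) > 0 && length(setdiff(g, q)) == 0) return("2A")
  if (length(supported) > 0) return("2B")
  "2C"
}

# Exact size (null rejection probability) of the two-sided exact binomial
# test at the given depth and null ratio, by enumeration.
exact_binomial_size <- function(depth, null_ratio = 0.5, alpha = 0.05) {
  x <- 0:depth
  pv <- vapply(x, function(k) {
    stats::binom.test(k, depth, null_ratio)$p.value
  }, numeric(1))
  sum(stats::dbinom(x[pv < alpha], depth, null_ratio))
}

# Exact power of the same test against success probability p_alt.
exact_binomial_power <- function(depth, p_alt, null_ratio = 0.5, alpha = 0.05) {
  x <- 0:depth
  pv <- vapply(x, function(k) {
    stats::binom.test(k, depth, null_ratio)$p.value
  }, numeric(1))
  sum(stats::dbinom(x[pv < alpha], depth, p_alt))
}
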