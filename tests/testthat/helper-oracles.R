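# Independent brute-force oracles, kept deliberately naive: they recompute
# every quantity term by term / element by element, sharing no code with the
# package implementations they check.

# RBO as a literal prefix-intersection sum.
oracle_rbo <- function(r, i, p, k) {
  total <- 0
  for (d in seq_len(k)) {
    rp <- r[seq_len(min(d, length(r)))]
    ip <- i[seq_len(min(d, length(i)))]
    total <- total + p^(d - 1) * length(intersect(rp, ip)) / d
  }
  (1 - p) * total
}

oracle_compatibility <- function(r, i, p, k) {
  if (length(i) == 0L) return(0)
  den <- oracle_rbo(i, i, p, k)
  if (den == 0) return(0)
  oracle_rbo(r, i, p, k) / den
}

# Reciprocal rank fusion by explicit per-document summation.
oracle_rrf <- function(lists, k) {
  docs <- sort(unique(unlist(lists)))
  score <- vapply(docs, function(d) {
    s <- 0
    for (l in lists) {
      pos <- which(l == d)
      if (length(pos) == 1L) s <- s + 1 / (k + pos)
    }
    s
  }, numeric(1))
  docs[order(-score, docs)]
}

# Stable three-way partition by label tier.
oracle_tier_partition <- function(doc_ids, labels, correct) {
  tier_of <- function(lab) if (lab == correct) 1L else if (lab == "neutral") 2L else 3L
  tiers <- vapply(labels, tier_of, integer(1))
  c(doc_ids[tiers == 1L], doc_ids[tiers == 2L], doc_ids[tiers == 3L])
}

# All permutations of a vector.
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (j in seq_along(v))
    for (rest in all_perms(v[-j]))
      out[[length(out) + 1L]] <- c(v[j], rest)
  out
}

# All ordered subsets of sizes in `sizes`.
ordered_subsets <- function(v, sizes) {
  out <- list(character(0))
  for (s in setdiff(sizes, 0L)) {
    for (comb in utils::combn(v, s, simplify = FALSE))
      out <- c(out, all_perms(comb))
  }
  out
}
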