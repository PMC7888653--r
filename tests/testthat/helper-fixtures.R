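# Small in-code fixtures shared across tests.

tiny_voc <- function(abundance, labels) {
  voc_table(abundance, labels)
}

# a taxa table with one obvious contaminant and one clean species
tiny_taxa <- function() {
  counts <- matrix(
    c(300, 280, 2, 1,    # "Ralstonia contamA": dominates the controls
      1, 0, 900, 800,    # "Lactobacillus cleanA": absent from controls
      5, 4, 600, 700),   # "Prevotella cleanB"
    nrow = 3, byrow = TRUE,
    dimnames = list(
      c("Ralstonia contamA", "Lactobacillus cleanA", "Prevotella cleanB"),
      c("NEG_01", "NEG_02", "S1", "S2")))
  taxa_table(counts, c(TRUE, TRUE, FALSE, FALSE),
             c(NA, NA, "cancer", "control"))
}

# brute-force Mann-Whitney U (pair counting, ties count 1/2)
brute_u <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# exact two-sided rank-sum p-value by enumerating all group assignments
enumerate_ranksum_p <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals)
  m <- length(x)
  obs <- brute_u(x, y)
  n2 <- length(y)
  mid <- m * n2 / 2
  combs <- utils::combn(n, m)
  us <- apply(combs, 2, function(idx) {
    brute_u(vals[idx], vals[-idx])
  })
  mean(abs(us - mid) >= abs(obs - mid) - 1e-9)
}

# AUC as the pairwise concordance statistic
brute_auc <- function(scores, labels) {
  ca <- scores[labels == "cancer"]
  co <- scores[labels == "control"]
  brute_u(ca, co) / (length(ca) * length(co))
}

# all root-to-tip branch lengths walked explicitly, for UniFrac oracles
brute_unifrac_pair <- function(tree, tips_a, tips_b) {
  n_tip <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  shared <- 0
  unique_len <- 0
  total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    below <- desc(tree$edge[e, 2])
    in_a <- any(below %in% tips_a)
    in_b <- any(below %in% tips_b)
    len <- tree$edge.length[e]
    if (in_a || in_b) total <- total + len
    if (xor(in_a, in_b)) unique_len <- unique_len + len
  }
  unique_len / total
}
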