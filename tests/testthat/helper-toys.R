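# Small fixtures built in code.

toy_adj <- function(n, edges) {
  x <- matrix(0L, n, n)
  for (e in edges) x[e[1], e[2]] <- 1L
  x
}

random_digraph <- function(n, p = 0.3) {
  x <- matrix(rbinom(n * n, 1, p), n, n)
  diag(x) <- 0L
  storage.mode(x) <- "integer"
  x
}

# A small multi-wave panel with full participation.
toy_panel <- function(n = 5, seed = 1, waves = 2, p = 0.25) {
  set.seed(seed)
  ws <- lapply(seq_len(waves), function(m)
    list(adjacency = random_digraph(n, p),
         behavior = sample.int(11, n, replace = TRUE)))
  wave_panel(ws)
}

all_net_effect_rows <- function() {
  rbind(
    data.frame(name = c("outdegree", "reciprocity", "transitive_triplets",
                        "transitive_recip_triplets", "outdegree_activity",
                        "indegree_activity"),
               covariate = NA_character_),
    data.frame(name = c("alter", "alter_sq", "ego", "ego_sq", "ego_x_alter",
                        "same"),
               covariate = "behavior"))
}
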