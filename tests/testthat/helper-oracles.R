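# Independent brute-force oracles. These re-derive every model quantity by
# direct enumeration over the definitions, with no code shared with the
# package internals, so package results can be checked against them.

toy3_tbl <- function() {
  tibble::tibble(
    id = paste0("e", 1:5),
    X = c(1, 1, 1, 0, 1),
    Y = c(0, 1, 0, 1, 1),
    Z = c(0, 0, 1, 1, 1),
    f = c(10, 20, 24, 8, 22)
  )
}

toy3_sample <- function() eco_sample(toy3_tbl())

toy3_p2 <- c(X = 1, Y = 2, Z = 2)

# motif of ecosystem a (row index): sorted set of groups of its species
oracle_motif <- function(P, g, a) {
  sort(unique(g[P[a, ] == 1]))
}

oracle_motif_key <- function(P, g) {
  vapply(
    seq_len(nrow(P)),
    function(a) paste(oracle_motif(P, g, a), collapse = "+"), character(1)
  )
}

# modelled value of ecosystem a: mean over its species of the mean observed
# function of ecosystems sharing its motif and containing that species
oracle_modelled_one <- function(P, F, g, a, exclude = integer(0)) {
  motif_a <- oracle_motif(P, g, a)
  same_motif <- setdiff(
    which(vapply(
      seq_len(nrow(P)),
      function(b) identical(oracle_motif(P, g, b), motif_a), logical(1)
    )),
    exclude
  )
  terms <- c()
  for (i in which(P[a, ] == 1)) {
    cluster <- same_motif[P[same_motif, i] == 1]
    if (length(cluster) > 0) terms <- c(terms, mean(F[cluster]))
  }
  if (length(terms) == 0) {
    return(NA_real_)
  }
  mean(terms)
}

oracle_modelled <- function(P, F, g) {
  vapply(seq_len(nrow(P)), function(a) oracle_modelled_one(P, F, g, a), numeric(1))
}

# leave-one-out prediction: NA when a is the sole representative of its motif
# or when no species term survives the depletion
oracle_loo <- function(P, F, g) {
  vapply(seq_len(nrow(P)), function(a) {
    motif_a <- oracle_motif(P, g, a)
    peers <- which(vapply(
      seq_len(nrow(P)),
      function(b) identical(oracle_motif(P, g, b), motif_a), logical(1)
    ))
    if (length(peers) == 1) {
      return(NA_real_)
    }
    oracle_modelled_one(P, F, g, a, exclude = a)
  }, numeric(1))
}

oracle_r2 <- function(P, F, g) {
  1 - sum((F - oracle_modelled(P, F, g))^2) / sum((F - mean(F))^2)
}

# all set partitions of 1..s, as lists of group-label vectors
enumerate_partitions <- function(s) {
  if (s == 1) {
    return(list(1L))
  }
  out <- list()
  for (p in enumerate_partitions(s - 1)) {
    for (grp in seq_len(max(p) + 1L)) out <- c(out, list(c(p, grp)))
  }
  out
}

# all partitions into exactly two non-empty groups
two_group_partitions <- function(s) {
  Filter(function(p) max(p) == 2L, enumerate_partitions(s))
}

oracle_best_2split <- function(P, F) {
  best <- -Inf
  best_p <- NULL
  for (p in two_group_partitions(ncol(P))) {
    r2 <- oracle_r2(P, F, p)
    if (r2 > best) {
      best <- r2
      best_p <- p
    }
  }
  list(partition = best_p, r_squared = best)
}

# random valid sample for property tests (every row non-empty)
random_sample <- function(n, s) {
  repeat {
    P <- matrix(rbinom(n * s, 1, 0.5), n, s)
    if (all(rowSums(P) > 0)) break
  }
  df <- tibble::as_tibble(as.data.frame(P))
  names(df) <- paste0("sp", seq_len(s))
  df <- dplyr::bind_cols(
    tibble::tibble(id = paste0("e", seq_len(n))),
    df,
    tibble::tibble(f = round(runif(n, 1, 100), 3))
  )
  eco_sample(df)
}

random_partition <- function(s, sigma) {
  repeat {
    g <- sample.int(sigma, s, replace = TRUE)
    if (length(unique(g)) == sigma) break
  }
  canonicalize_partition(g)
}
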