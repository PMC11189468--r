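# shared fixtures and independent brute-force oracles

# small, fast cohort configuration for unit tests
small_config <- function(seed = 1L, ...) {
  sim_config(n_patients = 120, n_genes_expressed = 400,
             n_low_expression_genes = 40, n_sex_linked_genes = 20,
             module_size_per_endotype = 20, n_prognostic_genes = 10,
             seed = seed, ...)
}

named_matrix <- function(values, n_genes, n_patients) {
  matrix(values, n_genes, n_patients,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("p%03d", seq_len(n_patients))))
}

# brute-force BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, input order
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(pmin(p[ord][i:m] * m / (i:m), 1))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# brute-force AUROC: explicit pair enumeration with half-credit ties
auroc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# brute-force enrichment score: literal walk of the running sum
es_brute <- function(stats, hit, weight_p = 1) {
  N <- length(stats)
  k <- sum(hit)
  w <- abs(stats[hit])^weight_p
  if (sum(w) == 0) w <- rep(1, k)
  running <- numeric(N)
  cur <- 0
  wi <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      wi <- wi + 1
      cur <- cur + w[wi] / sum(w)
    } else {
      cur <- cur - 1 / (N - k)
    }
    running[i] <- cur
  }
  # signed maximum deviation; exact magnitude ties resolve to the positive side
  m1 <- max(running)
  m2 <- min(running)
  if (m1 >= -m2 - 1e-12) m1 else m2
}

# quiet wrapper: preprocessing of a simulated cohort
prep_of <- function(sim) suppressWarnings(preprocess_counts(sim$counts))

geometric_mean_test <- function(x) exp(mean(log(x)))
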