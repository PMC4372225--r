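# Shared fixture builders and independent brute-force oracles.

tiny_records <- function() {
  tibble::tibble(
    compound_id = c("a", "a", "b", "c", "d"),
    smiles = c("CCO", "CCO", "CCN", "CCC", "CCCC"),
    ic50_nm = c(5, 50, 3, 400, 8)
  )
}

# Random binary fingerprint tibble with labels, for property tests.
random_fp_fixture <- function(n = 20, p = 5, seed = 1, prob = 0.5) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(n * p, 1L, prob), nrow = n)
    colnames(m) <- paste0("FP", seq_len(p))
    labels <- sample(c("inhibitor", "non_inhibitor"), n, replace = TRUE)
    # guarantee both classes
    labels[1] <- "inhibitor"; labels[2] <- "non_inhibitor"
    list(
      fp = dplyr::bind_cols(
        tibble::tibble(compound_id = sprintf("c%03d", seq_len(n))),
        tibble::as_tibble(m)
      ),
      labels = labels
    )
  })
}

# Brute-force per-class frequency: explicit loops over compounds.
oracle_frequencies <- function(fp, labels) {
  bits <- as.matrix(fp[setdiff(names(fp), "compound_id")])
  out <- data.frame(descriptor = colnames(bits), freq_active = NA_real_,
                    freq_inactive = NA_real_)
  for (j in seq_len(ncol(bits))) {
    ca <- 0; na <- 0; ci <- 0; ni <- 0
    for (i in seq_len(nrow(bits))) {
      if (labels[i] == "inhibitor") {
        na <- na + 1; ca <- ca + bits[i, j]
      } else {
        ni <- ni + 1; ci <- ci + bits[i, j]
      }
    }
    out$freq_active[j] <- 100 * ca / na
    out$freq_inactive[j] <- 100 * ci / ni
  }
  out
}

# Phi coefficient from the explicit 2x2 contingency table.
oracle_phi <- function(x, y) {
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  num <- n11 * n00 - n10 * n01
  den <- sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  if (den == 0) NA_real_ else num / den
}

# AUROC by exhaustive pair enumeration, ties counted one half.
oracle_auroc <- function(scores, truth) {
  pos <- scores[truth == "inhibitor"]
  neg <- scores[truth == "non_inhibitor"]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# Metrics by direct counting from a prediction vector.
oracle_metrics <- function(truth, pred) {
  tp <- sum(truth == "inhibitor" & pred == "inhibitor")
  fp <- sum(truth == "non_inhibitor" & pred == "inhibitor")
  tn <- sum(truth == "non_inhibitor" & pred == "non_inhibitor")
  fn <- sum(truth == "inhibitor" & pred == "non_inhibitor")
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / length(truth),
    mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den
  )
}

# A small clearly separable benchmark used across learner/CV tests.
separable_sim <- function(n = 60, seed = 7) {
  generate_synthetic(synthetic_spec(
    n_active = n, n_inactive = n, n_descriptors = 40,
    # 0.85/0.15 keeps the classes well separated while the planted bits'
    # pairwise phi (through the class variable) stays below the 0.6 filter
    planted_positive = data.frame(index = 1:6, p_active = 0.85, p_inactive = 0.15),
    planted_negative = data.frame(index = 7:12, p_active = 0.15, p_inactive = 0.85),
    background_p = 0.3, seed = seed
  ))
}
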