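# Random strictly positive composition matrices for property checks
rand_comp_matrix <- function(n, D, sd = 1) {
  M <- exp(matrix(rnorm(n * D, sd = sd), n, D))
  M <- M / rowSums(M)
  colnames(M) <- paste0("p", seq_len(D))
  M
}

rand_comp <- function(D, sd = 1) closure(exp(rnorm(D, sd = sd)))

# brute-force Aitchison distance straight from the definition
oracle_aitchison <- function(x, y) {
  lx <- log(x) - mean(log(x)); ly <- log(y) - mean(log(y))
  sqrt(sum((lx - ly)^2))
}

# brute-force balance value straight from the two-group definition
oracle_balance_value <- function(row, plus, minus) {
  r <- length(plus); s <- length(minus)
  sqrt(r * s / (r + s)) *
    log(prod(row[plus])^(1 / r) / prod(row[minus])^(1 / s))
}

# tiny well-formed profiles table: `acts` is a list of activity vectors
toy_profiles <- function(acts, soil = "PZ") {
  do.call(rbind, lapply(seq_along(acts), function(i) {
    a <- acts[[i]]
    data.frame(profile_id = sprintf("T%02d", i), soil_type = soil,
               horizon_order = seq_along(a),
               horizon_name = c("Ol", "Of", "Oh", "A", "Bbr", "C")[seq_along(a)],
               activity_bq_kg = a, stringsAsFactors = FALSE)
  }))
}
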