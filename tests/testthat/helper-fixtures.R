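# Shared fixtures and independent oracles.

# tiny long sample table: 2 varieties x 2 preparations x 2 replicates x
# 2 elements, values in ug/g
tiny_samples <- function() {
  tidyr::expand_grid(
    variety = c("A", "B"),
    preparation = c("cooked", "digestible"),
    replicate = 1:2,
    element = c("Al", "As")
  ) |>
    dplyr::mutate(
      value = ifelse(preparation == "cooked", 2e-3, 1e-3) *
        ifelse(element == "Al", 1, 0.02) *
        (1 + 0.05 * (replicate - 1)),
      unit = "ug/g"
    )
}

# brute-force KS sup-distance over the 2n step discontinuities
ks_d_oracle <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(pmax(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n))
}

# classical one-way ANOVA F computed from first principles
anova_f_oracle <- function(groups) {
  grand <- mean(unlist(groups))
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 1) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  dfb <- length(groups) - 1
  dfw <- sum(lengths(groups)) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# check the compact-letter-display defining property: two groups share a
# letter iff their pair is not significant
cld_property_holds <- function(letters_vec, sig_matrix) {
  gs <- names(letters_vec)
  for (i in seq_along(gs)) {
    for (j in seq_along(gs)) {
      if (i >= j) next
      share <- length(intersect(strsplit(letters_vec[[i]], "")[[1]],
                                strsplit(letters_vec[[j]], "")[[1]])) > 0
      if (share == sig_matrix[gs[i], gs[j]]) return(FALSE)
    }
  }
  all(nchar(letters_vec) >= 1)
}
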