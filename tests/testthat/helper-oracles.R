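# Independent oracles used across the suite. These deliberately retrace the
# science step by step (SI units, explicit molar bookkeeping, brute-force
# graph enumeration) rather than reusing any package internals.

# Stepwise ideal-gas respiration oracle, all in SI units.
oracle_respiration <- function(dco2_ppm, dw_g, t_hr, p_kpa, temp_k, vhs_l) {
  p_pa <- p_kpa * 1000
  v_m3 <- vhs_l / 1000
  n_gas_mol <- p_pa * v_m3 / (8.314 * temp_k)
  n_co2_mol <- n_gas_mol * dco2_ppm * 1e-6
  c_g <- n_co2_mol * 12.01
  c_ug <- c_g * 1e6
  c_ug / dw_g * (24 / t_hr)
}

# Molar amino-sugar partition oracle.
oracle_necromass <- function(muramic_ug, glcn_total_ug) {
  umol_mur <- muramic_ug / 251.23
  umol_glcn <- glcn_total_ug / 179.17
  umol_fungal_glcn <- umol_glcn - umol_mur
  fungal_glcn_ug <- umol_fungal_glcn * 179.17
  c(bacterial = muramic_ug * 45 / 1000, fungal = fungal_glcn_ug * 9 / 1000)
}

# Brute-force basis set: for every unordered non-adjacent pair, the claim is
# the pair plus the union of both vertices' parents. Returns a sorted
# character vector of canonical claim strings.
oracle_basis_claims <- function(vertices, edges) {
  claims <- character(0)
  n <- length(vertices)
  if (n < 2L) return(claims)
  adj <- matrix(FALSE, n, n, dimnames = list(vertices, vertices))
  for (k in seq_len(nrow(edges))) {
    adj[edges$from[k], edges$to[k]] <- TRUE
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      u <- vertices[i]; v <- vertices[j]
      if (adj[u, v] || adj[v, u]) next
      parents <- vertices[adj[, u] | adj[, v]]
      parents <- setdiff(parents, c(u, v))
      claims <- c(claims, paste(
        paste(sort(c(u, v)), collapse = "~"),
        paste(sort(parents), collapse = ","), sep = "|"))
    }
  }
  sort(claims)
}

canonical_claims <- function(claims) {
  sort(vapply(claims, function(cl) {
    paste(paste(sort(c(cl$x, cl$y)), collapse = "~"),
          paste(sort(cl$cond), collapse = ","), sep = "|")
  }, ""))
}

# Enumerate every labeled DAG on the given vertices: each unordered pair is
# absent, forward, or backward; keep acyclic orientations (checked by
# repeated sink elimination on the adjacency matrix).
enumerate_dags <- function(vertices) {
  n <- length(vertices)
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  states <- as.matrix(expand.grid(rep(list(0:2), m)))
  out <- list()
  for (r in seq_len(nrow(states))) {
    adj <- matrix(FALSE, n, n)
    st <- states[r, ]
    for (k in seq_len(m)) {
      if (st[k] == 1L) adj[pairs[1, k], pairs[2, k]] <- TRUE
      if (st[k] == 2L) adj[pairs[2, k], pairs[1, k]] <- TRUE
    }
    # acyclicity via repeated removal of sources
    a <- adj
    keep <- rep(TRUE, n)
    repeat {
      src <- keep & colSums(a[keep, , drop = FALSE]) == 0
      if (!any(src)) break
      keep[src] <- FALSE
      a[src, ] <- FALSE
      if (!any(keep)) break
    }
    if (any(keep)) next   # remaining vertices form a cycle
    idx <- which(adj, arr.ind = TRUE)
    if (nrow(idx) == 0L) next   # empty graph: no path model
    out[[length(out) + 1L]] <- data.frame(
      from = vertices[idx[, 1]], to = vertices[idx[, 2]],
      stringsAsFactors = FALSE)
  }
  out
}

# Small convenience: a design-shaped data frame of pure noise.
noise_plots <- function(n = 81, n_blocks = 4, seed = 1) {
  set.seed(seed)
  cfg <- synth_config(seed = seed)
  d <- generate_design(cfg)
  d$y <- rnorm(nrow(d))
  d
}
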