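# Independent brute-force oracles. These deliberately share no code path
# with the package: patterns are enumerated over every isotopologue
# combination, and decompositions loop over the full bounded lattice
# including hydrogen.

.oracle_electron <- 0.000548579909
.oracle_adducts <- list("+H" = c(H = 1), "+Na" = c(Na = 1),
                        "+NH4" = c(N = 1, H = 4))

# exhaustive isotopologue enumeration, aggregated by nominal-mass bin
oracle_pattern <- function(formula, adduct = NULL, prune = 1e-4) {
  el <- element_table()
  counts <- as_formula(formula)
  charged <- !is.null(adduct)
  if (charged) {
    add <- .oracle_adducts[[adduct]]
    for (s in names(add)) {
      cur <- if (s %in% names(counts)) counts[[s]] else 0L
      counts[s] <- cur + add[[s]]
    }
  }
  atoms <- rep(names(counts), counts)
  iso <- lapply(atoms, function(s) el[el$symbol == s, , drop = FALSE])
  grid <- expand.grid(lapply(iso, function(t) seq_len(nrow(t))),
                      KEEP.OUT.ATTRS = FALSE)
  mm <- mapply(function(t, idx) t$mass[idx], iso, grid)
  pp <- mapply(function(t, idx) t$abundance[idx], iso, grid)
  if (is.null(dim(mm))) { mm <- matrix(mm, nrow = nrow(grid)); pp <- matrix(pp, nrow = nrow(grid)) }
  mass <- rowSums(mm) - if (charged) .oracle_electron else 0
  prob <- apply(pp, 1, prod)
  k <- round(mass - min(mass))
  ab <- tapply(prob, k, sum)
  ctr <- tapply(prob * mass, k, sum) / ab
  ab <- ab / max(ab)
  keep <- ab >= prune
  ord <- order(ctr[keep])
  data.frame(mass = as.numeric(ctr[keep][ord]),
             abundance = as.numeric(ab[keep][ord]))
}

# naive exhaustive decomposition over the full bounded lattice
oracle_decompose <- function(mz, adduct, tol_ppm, bounds) {
  el <- element_table()
  mono <- vapply(split(el$mass, el$symbol), min, numeric(1))
  amass <- sum(.oracle_adducts[[adduct]] *
                 mono[names(.oracle_adducts[[adduct]])])
  win <- tol_ppm * 1e-6 * mz
  hits <- character(0)
  for (C in bounds$C[1]:bounds$C[2])
    for (H in bounds$H[1]:bounds$H[2])
      for (N in bounds$N[1]:bounds$N[2])
        for (O in bounds$O[1]:bounds$O[2])
          for (Na in bounds$Na[1]:bounds$Na[2]) {
            m <- C * mono[["C"]] + H * mono[["H"]] + N * mono[["N"]] +
              O * mono[["O"]] + Na * mono[["Na"]] + amass - .oracle_electron
            if (abs(m - mz) <= win)
              hits <- c(hits, format_formula(c(C = C, H = H, N = N,
                                               O = O, Na = Na)))
          }
  sort(unique(hits))
}

# quick scan-series builder from per-species constant or supplied traces
make_series <- function(mz, traces, axis, axis_kind = "potential", ...) {
  peaks <- do.call(rbind, lapply(seq_along(mz), function(i)
    data.frame(axis_value = axis, mz = mz[i], intensity = traces[[i]])))
  scan_series(peaks, axis_kind = axis_kind, ...)
}

tp_tab <- mon_tp_table()
tp_rows <- tp_tab[startsWith(tp_tab$id, "TP"), ]
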