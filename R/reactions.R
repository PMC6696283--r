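# Elementary transformation reactions and path enumeration.
#
# Reactions are expressed as net element-count changes (a decarboxylation
# R-COOH -> R-H is net -CO2; an O-demethylation OCH3 -> OH is net -CH2).
# A transformation path is a multiset of steps whose summed delta equals
# the element difference between parent and product; step order is never
# meaningful at formula level.

.element_order <- c("C", "H", "N", "O", "Na")

# delta as a fixed-length numeric vector for matrix arithmetic
full_delta <- function(d) {
  v <- stats::setNames(numeric(length(.element_order)), .element_order)
  if (length(d)) v[names(d)] <- d
  v
}

#' Default elementary reaction steps
#'
#' The reaction alphabet covering oxidative (electrochemical, microsomal)
#' and hydrolytic chemistry of polyether drugs: decarboxylation,
#' (de)methylation, (de)hydrogenation, hydration/dehydration, methanol
#' addition, and formula-neutral isomerization (ring opening or
#' diastereomerization).
#'
#' @return Named list of signed element-count deltas.
#' @export
reaction_steps <- function() {
  list(
    DECARBOXYLATION   = c(C = -1L, O = -2L),
    DEMETHYLATION     = c(C = -1L, H = -2L),
    METHYLATION       = c(C = 1L, H = 2L),
    DEHYDROGENATION   = c(H = -2L),
    HYDROGENATION     = c(H = 2L),
    HYDRATION         = c(H = 2L, O = 1L),
    DEHYDRATION       = c(H = -2L, O = -1L),
    METHANOL_ADDITION = c(C = 1L, H = 4L, O = 1L),
    ISOMERIZATION     = c()
  )
}

# canonical non-decreasing index multisets of size k over n items
step_multisets <- function(n, k) {
  if (k == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), k)))
  keep <- rowSums(grid[, -1L, drop = FALSE] < grid[, -k, drop = FALSE]) == 0L
  grid[keep, , drop = FALSE]
}

# TRUE when a nonempty proper sub-multiset of the steps sums to zero
# (a no-op cycle such as hydration + dehydration)
has_noop_subset <- function(idx, deltas) {
  k <- length(idx)
  if (k < 2L) return(FALSE)
  for (mask in seq_len(2L^k - 2L)) {
    sel <- as.logical(bitwAnd(mask, 2L^(seq_len(k) - 1L)))
    if (all(colSums(deltas[idx[sel], , drop = FALSE]) == 0)) return(TRUE)
  }
  FALSE
}

#' Enumerate transformation paths between two formulas
#'
#' Finds every multiset of at most `max_steps` elementary reactions whose
#' summed element delta equals `formula_diff(parent, product)`. Paths that
#' contain a no-op sub-cycle (a nonempty proper sub-multiset of steps
#' summing to zero, e.g. hydration followed by dehydration) are pruned:
#' a strictly shorter equivalent path always exists. Identical formulas
#' yield the single path ISOMERIZATION.
#'
#' @param parent,product Formulas (strings or named counts).
#' @param max_steps Maximum path length, between 0 and 4.
#' @param steps Reaction alphabet, as from [reaction_steps()].
#' @return A list of paths sorted by (step count, canonical label); each is
#'   a list with `steps` (sorted step names), `label` (the canonical
#'   " + "-joined concatenation), `n_steps` and `delta`. Empty list when no
#'   combination explains the difference.
#' @export
#' @examples
#' enumerate_paths("C36H62O11", "C35H60O9")   # decarboxylation + dehydrogenation
enumerate_paths <- function(parent, product, max_steps = 3L,
                            steps = reaction_steps()) {
  if (max_steps < 0L || max_steps > 4L)
    stop("max_steps must lie in [0, 4]")
  delta <- full_delta(formula_diff(parent, product))
  if (all(delta == 0)) {
    p <- list(steps = "ISOMERIZATION", label = "ISOMERIZATION",
              n_steps = 1L, delta = delta)
    return(list(p))
  }
  active <- steps[vapply(steps, length, integer(1)) > 0L]
  if (!length(active) || max_steps == 0L) return(list())
  dmat <- t(vapply(active, full_delta, numeric(length(.element_order))))
  paths <- list()
  for (k in seq_len(max_steps)) {
    ms <- step_multisets(nrow(dmat), k)
    if (!nrow(ms)) next
    sums <- apply(ms, 1L, function(idx) colSums(dmat[idx, , drop = FALSE]))
    hit <- which(colSums(abs(sums - delta)) == 0)
    for (i in hit) {
      idx <- ms[i, ]
      if (has_noop_subset(idx, dmat)) next
      nm <- sort(rownames(dmat)[idx])
      paths[[length(paths) + 1L]] <- list(
        steps = nm, label = paste(nm, collapse = " + "),
        n_steps = k, delta = delta)
    }
  }
  ord <- order(vapply(paths, `[[`, integer(1), "n_steps"),
               vapply(paths, `[[`, character(1), "label"))
  paths[ord]
}

#' Minimal transformation path label
#'
#' Convenience wrapper: the label of the shortest (first-ranked) path from
#' [enumerate_paths()], or `NA` when none exists within `max_steps`.
#'
#' @inheritParams enumerate_paths
#' @return A single character label or `NA_character_`.
#' @export
minimal_path_label <- function(parent, product, max_steps = 3L,
                               steps = reaction_steps()) {
  p <- enumerate_paths(parent, product, max_steps = max_steps, steps = steps)
  if (!length(p)) NA_character_ else p[[1L]]$label
}

#' Build a suspect list of transformation products
#'
#' Applies every multiset of at most `max_steps` reactions to each parent,
#' keeps products with all-non-negative element counts, deduplicates
#' formulas across parents (shortest path wins; ties go to the earlier
#' parent in `parents`) and emits one row per adduct with the expected m/z.
#' The parents themselves are always included (label ISOMERIZATION,
#' 0 steps).
#'
#' @param parents Character vector or list of parent formulas, most
#'   abundant first (ties in path length resolve to the earlier parent).
#' @param steps Reaction alphabet.
#' @param max_steps Maximum number of steps per product.
#' @param adducts Adduct species to pair each suspect with.
#' @return A data.frame with columns `formula`, `parent`, `path_label`,
#'   `n_steps`, `adduct`, `mz_calc`.
#' @export
#' @examples
#' suspect_list("C36H62O11", max_steps = 1, adducts = "+Na")
suspect_list <- function(parents, steps = reaction_steps(), max_steps = 3L,
                         adducts = c("+Na", "+NH4")) {
  if (!length(parents)) stop("at least one parent formula is required")
  if (max_steps < 0L || max_steps > 4L)
    stop("max_steps must lie in [0, 4]")
  parents <- vapply(parents, function(p) format_formula(p), character(1),
                    USE.NAMES = FALSE)
  adducts <- vapply(adducts, normalize_adduct, character(1),
                    USE.NAMES = FALSE)
  active <- steps[vapply(steps, length, integer(1)) > 0L]
  dmat <- t(vapply(active, full_delta, numeric(length(.element_order))))
  rows <- list()
  for (pi in seq_along(parents)) {
    pf <- full_delta(as_formula(parents[pi]))
    rows[[length(rows) + 1L]] <- data.frame(
      formula = parents[pi], parent = parents[pi],
      path_label = "ISOMERIZATION", n_steps = 0L,
      stringsAsFactors = FALSE)
    for (k in seq_len(max_steps)) {
      ms <- step_multisets(nrow(dmat), k)
      for (i in seq_len(nrow(ms))) {
        idx <- ms[i, ]
        if (has_noop_subset(idx, dmat)) next
        d <- colSums(dmat[idx, , drop = FALSE])
        if (all(d == 0)) next
        prod_counts <- pf + d
        if (any(prod_counts < 0)) next
        nm <- sort(rownames(dmat)[idx])
        rows[[length(rows) + 1L]] <- data.frame(
          formula = format_formula(stats::setNames(as.integer(prod_counts),
                                                   .element_order)),
          parent = parents[pi],
          path_label = paste(nm, collapse = " + "),
          n_steps = k, stringsAsFactors = FALSE)
      }
    }
  }
  sus <- do.call(rbind, rows)
  parent_rank <- match(sus$parent, parents)
  sus <- sus[order(sus$formula, sus$n_steps, parent_rank, sus$path_label), ,
             drop = FALSE]
  sus <- sus[!duplicated(sus$formula), , drop = FALSE]
  out <- do.call(rbind, lapply(adducts, function(a) {
    s <- sus
    s$adduct <- a
    s$mz_calc <- vapply(s$formula, function(f) adduct_mz(f, a), numeric(1),
                        USE.NAMES = FALSE)
    s
  }))
  out <- out[order(out$formula, out$adduct), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group TP records into structural classes
#'
#' The class key is the canonical minimal-path label of each record relative
#' to its own parent, refined by the record's isomer annotation. Records
#' that share a key collapse into one class: stereoisomer pairs (same
#' formula, same path, different retention) count once, whereas
#' formula-neutral isomers with different chemistry (a diastereomer vs a
#' ring-opened product) stay distinct through their annotations. The same
#' transformation applied to two homologous parents is one class, matching
#' how structurally different TPs are counted in suspect screening studies.
#'
#' @param records A data.frame with columns `formula`, `parent` (parent
#'   neutral formula; must be non-missing) and optionally
#'   `isomer_annotation` (empty string when inapplicable) and `id`.
#' @param max_steps Passed to the path search.
#' @param steps Reaction alphabet.
#' @return A list with `n_classes`, `classes` (a data.frame mapping records
#'   to class keys) and `members` (record ids per class).
#' @export
structural_classes <- function(records, max_steps = 3L,
                               steps = reaction_steps()) {
  if (!is.data.frame(records) || !all(c("formula", "parent") %in% names(records)))
    stop("records must be a data.frame with 'formula' and 'parent' columns")
  if (!nrow(records)) stop("no records to classify")
  if (any(is.na(records$parent) | !nzchar(records$parent)))
    stop("every record needs a parent assignment")
  ann <- if ("isomer_annotation" %in% names(records))
    ifelse(is.na(records$isomer_annotation), "", records$isomer_annotation)
  else rep("", nrow(records))
  # stereoisomers of one another share a path; collapse them via a common key
  ann[ann == "stereoisomer"] <- ""
  labels <- vapply(seq_len(nrow(records)), function(i) {
    lab <- minimal_path_label(records$parent[i], records$formula[i],
                              max_steps = max_steps, steps = steps)
    if (is.na(lab))
      lab <- paste0("UNEXPLAINED[",
                    format_formula(formula_diff(records$parent[i],
                                                records$formula[i])), "]")
    lab
  }, character(1))
  key <- ifelse(nzchar(ann), paste0(labels, " (", ann, ")"), labels)
  ids <- if ("id" %in% names(records)) records$id else
    as.character(seq_len(nrow(records)))
  classes <- data.frame(id = ids, path_label = labels,
                        isomer_annotation = ann, class = key,
                        stringsAsFactors = FALSE)
  list(n_classes = length(unique(key)), classes = classes,
       members = split(ids, key))
}
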