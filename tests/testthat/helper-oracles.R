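# Independent flood-fill oracle for connected-component labeling: iterative
# minimum-label propagation over shifted copies until fixpoint. Deliberately
# a different algorithm from the package's BFS labeling.
oracle_label <- function(mask, connectivity = 8) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(Inf, n, m)
  lab[mask] <- which(mask)
  offsets <- if (connectivity == 8) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
         c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  shift <- function(x, di, dj) {
    out <- matrix(Inf, n, m)
    rs <- max(1, 1 + di):min(n, n + di)
    ro <- max(1, 1 - di):min(n, n - di)
    cs <- max(1, 1 + dj):min(m, m + dj)
    co <- max(1, 1 - dj):min(m, m - dj)
    out[ro, co] <- x[rs, cs]
    out
  }
  repeat {
    new <- lab
    for (o in offsets) new <- pmin(new, shift(lab, o[1], o[2]))
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

# Oracle particle filter built on oracle_label: keep components >= min_px.
oracle_filter <- function(mask, min_px = 3, connectivity = 8) {
  lab <- oracle_label(mask, connectivity)
  ids <- lab[is.finite(lab)]
  sizes <- table(ids)
  keep_ids <- as.numeric(names(sizes)[sizes >= min_px])
  list(mask = matrix(lab %in% keep_ids, nrow(mask), ncol(mask)),
       particle_count = length(keep_ids))
}

# Small deterministic structural/OCTA pair with a known bright block. The
# block must stay under ~20% of its quadrant or the mean + 2 SD threshold of
# a two-level histogram exceeds the bright level and the HSS mask is empty.
make_test_pair <- function(n = 16, block = 3:5, struct_on = 180,
                           struct_off = 120, octa_on = 220, octa_off = 20) {
  octa <- matrix(octa_off, n, n)
  octa[block, block] <- octa_on
  st <- matrix(struct_off, n, n)
  st[block, block] <- struct_on
  list(structural = enface_image(st, "structural"),
       octa = enface_image(octa, "angiography"))
}
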