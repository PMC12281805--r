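# Independent brute-force persistence oracle: full mod-2 boundary-matrix
# reduction over every simplex of dimension <= 2, with explicit global
# simplex ordering. Deliberately shares no code with the package's
# union-find / dual-reduction implementation.
brute_vr_persistence <- function(D, threshold = Inf) {
  n <- nrow(D)
  simp <- list()
  for (i in seq_len(n)) simp[[length(simp) + 1]] <-
    list(dim = 0L, val = 0, v = i)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (D[i, j] <= threshold)
      simp[[length(simp) + 1]] <- list(dim = 1L, val = D[i, j], v = c(i, j))
  if (n >= 3)
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      d <- max(D[i, j], D[i, k], D[j, k])
      if (d <= threshold)
        simp[[length(simp) + 1]] <- list(dim = 2L, val = d, v = c(i, j, k))
    }
  # global filtration order: value, then dimension (faces first), then lex
  vals <- vapply(simp, `[[`, numeric(1), "val")
  dims <- vapply(simp, `[[`, integer(1), "dim")
  lex <- vapply(simp, function(s)
    paste(sprintf("%06d", s$v), collapse = ","), character(1))
  ord <- order(vals, dims, lex)
  simp <- simp[ord]
  pos <- new.env()
  for (s in seq_along(simp))
    assign(paste(simp[[s]]$dim, paste(simp[[s]]$v, collapse = ","), sep = ":"),
           s, envir = pos)
  lookup <- function(dim, v)
    get(paste(dim, paste(v, collapse = ","), sep = ":"), envir = pos)

  cols <- lapply(simp, function(s) {
    if (s$dim == 0L) return(integer(0))
    faces <- if (s$dim == 1L) as.list(s$v) else
      list(s$v[c(1, 2)], s$v[c(1, 3)], s$v[c(2, 3)])
    sort(vapply(faces, function(f) lookup(s$dim - 1L, f), integer(1)))
  })

  low_owner <- integer(length(simp))  # 0 = unowned
  pairs <- list()
  for (cidx in seq_along(cols)) {
    col <- cols[[cidx]]
    while (length(col) > 0) {
      lw <- max(col)
      if (low_owner[lw] == 0) break
      other <- cols[[low_owner[lw]]]
      col <- sort(union(setdiff(col, other), setdiff(other, col)))
    }
    cols[[cidx]] <- col
    if (length(col) > 0) {
      lw <- max(col)
      low_owner[lw] <- cidx
      pairs[[length(pairs) + 1]] <- c(lw, cidx)
    }
  }
  rows <- lapply(pairs, function(p) {
    birth_s <- simp[[p[1]]]
    death_s <- simp[[p[2]]]
    data.frame(hom_dim = birth_s$dim, birth = birth_s$val,
               death = death_s$val)
  })
  out <- do.call(rbind, c(rows, list(data.frame(hom_dim = integer(0),
                                                birth = numeric(0),
                                                death = numeric(0)))))
  out <- out[out$death > out$birth & out$hom_dim <= 1, , drop = FALSE]
  out[order(out$hom_dim, out$birth, out$death), , drop = FALSE]
}

sort_diagram <- function(diag) {
  df <- as.data.frame(diag)[, c("hom_dim", "birth", "death")]
  df <- df[order(df$hom_dim, df$birth, df$death), , drop = FALSE]
  rownames(df) <- NULL
  df
}
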