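#' Persistence-diagram descriptor vector
#'
#' Summarizes a finalized persistence diagram into a named one-row
#' data.frame of scalar topological descriptors per homological dimension
#' `i` in `{0, 1}`:
#'
#' * `betti` / `betti_norm` — number of finite intervals and its ratio to
#'   the number of points;
#' * `lifetime_{min,max,avg,std,sum}` — aggregates of the lifetimes
#'   `delta_j = death_j - birth_j`;
#' * `lifetime_norm_*` — the same aggregates of the normalized lifetimes
#'   `p_j = delta_j / sum(delta)`;
#' * `midlife_*` and `midlife_norm_*` — aggregates of the midlifes
#'   `mu_j = (birth_j + death_j)/2` and of `nu_j = mu_j / sum(mu)`;
#' * `entropy` — persistence entropy `-sum p_j log p_j` (natural log).
#'
#' Standard deviations are population standard deviations, so a single
#' interval gives `std = 0`. A homological dimension with no intervals
#' yields `NA` for all its fields (no topological signal — not a failure).
#'
#' @param diag a [vr_persistence()] diagram (finalized: no infinite bars).
#' @return one-row data.frame of class `topo_descriptors`, columns prefixed
#'   `h0_` / `h1_`, plus `n_points`.
#' @export
compute_descriptors <- function(diag) {
  stopifnot(inherits(diag, "persistence_diagram"))
  n_points <- attr(diag, "n_points")
  aggs <- c(min = min, max = max, avg = mean, std = pop_sd, sum = sum)

  one_dim <- function(i) {
    sub <- diag[diag$hom_dim == i, , drop = FALSE]
    m <- nrow(sub)
    fields <- c("betti", "betti_norm",
                paste0("lifetime_", names(aggs)),
                paste0("lifetime_norm_", names(aggs)),
                paste0("midlife_", names(aggs)),
                paste0("midlife_norm_", names(aggs)),
                "entropy")
    out <- stats::setNames(rep(NA_real_, length(fields)), fields)
    if (m == 0) return(out)
    lt <- sub$death - sub$birth
    ml <- (sub$birth + sub$death) / 2
    p <- lt / sum(lt)
    nu <- if (sum(ml) > 0) ml / sum(ml) else rep(NA_real_, m)
    out["betti"] <- m
    out["betti_norm"] <- m / n_points
    for (a in names(aggs)) {
      out[paste0("lifetime_", a)] <- aggs[[a]](lt)
      out[paste0("lifetime_norm_", a)] <- aggs[[a]](p)
      out[paste0("midlife_", a)] <- aggs[[a]](ml)
      out[paste0("midlife_norm_", a)] <- aggs[[a]](nu)
    }
    out["entropy"] <- -sum(p * log(p))
    out
  }

  h0 <- one_dim(0L)
  h1 <- one_dim(1L)
  res <- c(stats::setNames(h0, paste0("h0_", names(h0))),
           stats::setNames(h1, paste0("h1_", names(h1))),
           n_points = n_points)
  out <- as.data.frame(as.list(res))
  class(out) <- c("topo_descriptors", "data.frame")
  out
}
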