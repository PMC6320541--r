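check_incidence <- function(m, min_rows = 1L) {
  if (!is.matrix(m) || !is.numeric(m)) abort("incidence matrix must be a numeric matrix")
  if (nrow(m) < min_rows) {
    abort(sprintf("incidence matrix needs at least %d collection(s), has %d",
                  min_rows, nrow(m)))
  }
  if (any(m != 0L & m != 1L)) abort("incidence matrix entries must be 0/1")
  invisible(m)
}

#' Alpha diversity: mean species richness per collection
#'
#' @param m Binary incidence matrix (collections x species).
#' @return Mean of the row sums.
#' @export
#' @examples
#' alpha_mean(rbind(c(1, 1, 1), c(0, 1, 1)))
alpha_mean <- function(m) {
  check_incidence(m)
  mean(rowSums(m))
}

#' Gamma diversity: total species richness
#'
#' @param m Binary incidence matrix.
#' @return Number of species present in at least one collection.
#' @export
gamma_total <- function(m) {
  check_incidence(m)
  sum(colSums(m) > 0)
}

#' Whittaker's beta: gamma over mean alpha
#'
#' @param m Binary incidence matrix.
#' @return `gamma_total(m) / alpha_mean(m)`; 1 when all collections are
#'   identical, N for N disjoint equally rich collections.
#' @export
whittaker_beta <- function(m) {
  gamma_total(m) / alpha_mean(m)
}

#' Pairwise Simpson dissimilarity between two species sets
#'
#' `min(b, c) / (a + min(b, c))` where `a` is the number of shared species and
#' `b`, `c` the numbers unique to each site. Zero whenever one assemblage is
#' nested in the other (turnover, not richness difference); one for disjoint
#' assemblages.
#'
#' @param site_i,site_j Species sets: character vectors of species, or 0/1
#'   incidence vectors over a common species order.
#' @return Dissimilarity in \[0, 1\].
#' @export
#' @examples
#' pairwise_simpson(c("a", "b", "c"), c("b", "c", "d"))
pairwise_simpson <- function(site_i, site_j) {
  if (is.numeric(site_i) && is.numeric(site_j)) {
    if (length(site_i) != length(site_j)) abort("incidence vectors must share length")
    site_i <- which(site_i > 0)
    site_j <- which(site_j > 0)
  }
  if (length(site_i) == 0L || length(site_j) == 0L) abort("both sites must be non-empty")
  a <- length(intersect(site_i, site_j))
  b <- length(setdiff(site_i, site_j))
  cc <- length(setdiff(site_j, site_i))
  m <- min(b, cc)
  if (a + m == 0L) return(0)
  m / (a + m)
}

#' Multiple-site Simpson dissimilarity
#'
#' The multiple-site generalization of the pairwise Simpson index:
#' \deqn{\beta_{SIM} = \frac{\sum_{i<j}\min(b_{ij}, b_{ji})}
#'   {\left(\sum_i S_i - S_T\right) + \sum_{i<j}\min(b_{ij}, b_{ji})}}
#' with \eqn{S_i} the richness of site \eqn{i}, \eqn{S_T} the pooled richness,
#' and \eqn{b_{ij}} the number of species present in site \eqn{i} but absent
#' from site \eqn{j}. It isolates spatial turnover: 0 when all collections are
#' compositionally identical (or perfectly nested), 1 when no two collections
#' share a species. For exactly two sites it reduces to [pairwise_simpson()].
#'
#' This is what the package (and the paleontological literature) calls
#' "Simpson's metric" -- a dissimilarity of the Simpson/Baselga family, not
#' Simpson's diversity index.
#'
#' @param m Binary incidence matrix with at least 2 non-empty rows.
#' @return Dissimilarity in \[0, 1\].
#' @export
#' @examples
#' m <- rbind(c(1, 1, 1, 0, 0, 0), c(0, 1, 1, 1, 0, 0), c(0, 0, 0, 0, 1, 1))
#' multisite_simpson(m)  # 5/7
multisite_simpson <- function(m) {
  check_incidence(m, min_rows = 2L)
  if (any(rowSums(m) == 0)) abort("all collections must contain at least one species")
  storage.mode(m) <- "double"
  S <- rowSums(m)
  shared <- tcrossprod(m)          # a_ij = shared species between rows i and j
  b <- S - shared                  # b_ij = species in i absent from j
  minb <- pmin(b, t(b))
  sum_min <- sum(minb[upper.tri(minb)])
  nest <- sum(S) - sum(colSums(m) > 0)
  if (sum_min == 0) return(0)      # identical or perfectly nested collections
  sum_min / (nest + sum_min)
}

#' All four diversity components of one incidence matrix
#'
#' @param m Binary incidence matrix (>= 2 collections for the beta metrics).
#' @return One-row tibble with columns `alpha`, `gamma`, `beta_w`, `beta_sim`.
#' @export
diversity_values <- function(m) {
  tibble::tibble(
    alpha = alpha_mean(m),
    gamma = gamma_total(m),
    beta_w = whittaker_beta(m),
    beta_sim = multisite_simpson(m)
  )
}
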