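#' Pairwise Hamming and p-distance matrix of haplotypes
#'
#' @param haplotypes character vector of equal-length strings over 0/1
#'   (optionally named), or a complete-case [haplotype_matrix()].
#' @return list of class `"hap_dist"`: `steps` (integer Hamming matrix),
#'   `p` (steps / n_sites), `labels`, `n_sites`.
#' @export
#' @examples
#' hamming_matrix(c(h1 = "0101", h2 = "0110"))$steps
hamming_matrix <- function(haplotypes) {
  if (inherits(haplotypes, "haplotype_matrix")) {
    x <- haplotypes$alleles
    if (anyNA(x)) stop("haplotypes must be complete (no missing entries)")
    labels <- rownames(x)
  } else {
    if (length(unique(nchar(haplotypes))) > 1L) {
      stop("haplotypes must have equal length")
    }
    labels <- names(haplotypes) %||% paste0("h", seq_along(haplotypes))
    x <- do.call(rbind, lapply(strsplit(haplotypes, ""), as.integer))
    if (length(haplotypes) == 0L) x <- matrix(integer(), 0, 0)
    if (anyNA(x)) stop("haplotypes must contain only 0 and 1")
  }
  m <- ncol(x)
  steps <- tcrossprod(x, 1 - x) + tcrossprod(1 - x, x)
  storage.mode(steps) <- "integer"
  dimnames(steps) <- list(labels, labels)
  out <- list(steps = steps, p = steps / m, labels = labels, n_sites = m)
  class(out) <- "hap_dist"
  out
}

#' Probability that observed differences are free of superimposed changes
#'
#' Statistical parsimony asks, for two haplotypes differing at `j` of `m`
#' sites, how likely it is that each observed difference reflects exactly one
#' substitution (no multiple hits hiding extra mutational steps). This
#' estimator builds the probability stepwise: the i-th accumulated difference
#' is a single hit with probability \eqn{s(i/m)}, where under a Jukes-Cantor
#' finite-sites model with per-site substitution load \eqn{\mu(q) = -3/4
#' \log(1 - 4q/3)} at observed per-site divergence \eqn{q},
#' \deqn{s(q) = \frac{\mu(q) e^{-\mu(q)}}{q}.}
#' The parsimony probability after j steps is the product
#' \eqn{P_j = \prod_{i=1}^{j} s(i/m)} (so \eqn{P} is computed by recursion
#' \eqn{P_j = P_{j-1} s(j/m)}). Beyond the Jukes-Cantor saturation point
#' (q >= 3/4) the per-step factor is held at its saturation value so that
#' \eqn{P_j} stays positive but negligible.
#'
#' @param steps number of observed differences (vectorized).
#' @param n_sites haplotype length in variant sites.
#' @return numeric vector of parsimony probabilities.
#' @seealso [parsimony_connection_limit()]
#' @export
parsimony_probability <- function(steps, n_sites) {
  stopifnot(n_sites >= 1, all(steps >= 0))
  q_all <- pmin(seq_len(max(steps, 1)) / n_sites, 0.749999)
  mu <- -0.75 * log1p(-4 * q_all / 3)
  s <- mu * exp(-mu) / q_all
  cp <- cumprod(s)
  ifelse(steps == 0, 1, cp[steps])
}

#' 95% statistical-parsimony connection limit
#'
#' The largest number of mutational steps `j` for which the parsimony
#' probability [parsimony_probability()] is at least `confidence`; haplotype
#' pairs farther apart than the limit are not connected in the network. For
#' 115 variant sites at 95% confidence the limit is 5 steps, which joins
#' within-strain haplotype pairs (p-distance about 0.03-0.04) while keeping
#' strains at p >= 0.114 (14+ steps) in separate networks.
#'
#' @param n_sites haplotype length in variant sites.
#' @param confidence required parsimony probability, in (0, 1).
#' @return integer connection limit (possibly 0 for very short sequences or
#'   very high confidence).
#' @export
#' @examples
#' parsimony_connection_limit(115, 0.95)
parsimony_connection_limit <- function(n_sites, confidence = 0.95) {
  stopifnot(n_sites >= 1, confidence > 0, confidence < 1)
  p <- parsimony_probability(seq_len(n_sites), n_sites)
  ok <- which(p >= confidence)
  if (length(ok) == 0L) 0L else max(ok)
}

# Deterministic Kruskal MST within one component: candidate edges sorted by
# (steps, -joint multiplicity, labels) so tie-breaking is reproducible.
mst_edges <- function(edges, multiplicity) {
  if (nrow(edges) == 0L) return(edges[0, , drop = FALSE])
  jm <- multiplicity[edges$from] + multiplicity[edges$to]
  ord <- order(edges$steps, -jm, edges$from, edges$to)
  edges <- edges[ord, , drop = FALSE]
  parent <- stats::setNames(names(multiplicity), names(multiplicity))
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  keep <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$from[i]); rb <- find(edges$to[i])
    if (ra != rb) {
      parent[[ra]] <- rb
      keep[i] <- TRUE
    }
  }
  edges[keep, , drop = FALSE]
}

#' Build a statistical-parsimony haplotype network
#'
#' Connects every haplotype pair at Hamming distance `<= limit`; strains are
#' the connected components of that graph. Within each component the
#' rendered edges form a minimum spanning structure (Kruskal on step counts;
#' ties broken by higher joint multiplicity, then lexical label order) and
#' edges spanning `s >= 2` steps contribute `s - 1` inferred intermediate
#' nodes — a rendering count only, never part of components or statistics.
#'
#' @param dist a `"hap_dist"` from [hamming_matrix()].
#' @param multiplicities named integer vector of individuals per haplotype
#'   (default 1 each).
#' @param limit connection limit in steps; default
#'   `parsimony_connection_limit(n_sites, 0.95)`.
#' @return object of class `"haplotype_network"`: `nodes` (label,
#'   multiplicity, component), `edges` (from, to, steps, in_mst,
#'   inferred_nodes), `membership`, `connection_limit`, `n_sites`.
#' @export
build_network <- function(dist, multiplicities = NULL, limit = NULL) {
  stopifnot(inherits(dist, "hap_dist"))
  limit <- limit %||% parsimony_connection_limit(dist$n_sites, 0.95)
  stopifnot(limit >= 1)
  labels <- dist$labels
  multiplicities <- multiplicities %||% setNames(rep(1L, length(labels)), labels)
  if (!all(labels %in% names(multiplicities))) {
    stop("multiplicities must be named for every haplotype")
  }
  multiplicities <- multiplicities[labels]
  idx <- which(upper.tri(dist$steps) & dist$steps <= limit, arr.ind = TRUE)
  edges <- data.frame(from = labels[idx[, 1]], to = labels[idx[, 2]],
                      steps = dist$steps[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = labels))
  comp <- igraph::components(g)
  membership <- setNames(as.integer(comp$membership), labels)
  mst <- do.call(rbind, lapply(seq_len(comp$no), function(k) {
    in_k <- labels[membership == k]
    e_k <- edges[edges$from %in% in_k & edges$to %in% in_k, , drop = FALSE]
    mst_edges(e_k, multiplicities[in_k])
  }))
  if (is.null(mst)) mst <- edges[0, , drop = FALSE]
  key <- paste(edges$from, edges$to)
  edges$in_mst <- key %in% paste(mst$from, mst$to)
  edges$inferred_nodes <- ifelse(edges$in_mst, pmax(edges$steps - 1L, 0L), 0L)
  nodes <- data.frame(label = labels,
                      multiplicity = as.integer(multiplicities),
                      component = membership, stringsAsFactors = FALSE)
  out <- list(nodes = nodes, edges = edges, membership = membership,
              connection_limit = limit, n_sites = dist$n_sites)
  class(out) <- "haplotype_network"
  out
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype_network: %d haplotypes, %d components, connection limit %d steps\n",
              nrow(x$nodes), max(x$membership), x$connection_limit))
  invisible(x)
}

#' Assign haplotypes and individuals to strains
#'
#' One strain per network component; strains are labeled `A`, `B`, `C`, ...
#' by decreasing number of carrying individuals. Components carrying fewer
#' than `min_major` individuals are flagged rare — in real surveys these are
#' the singleton strains outside the major networks.
#'
#' @param network a [build_network()] result.
#' @param individual_haplotypes data.frame `individual_id`, `haplotype`
#'   (haplotype labels as in the network).
#' @param min_major minimum individuals for a major strain.
#' @return object of class `"strain_assignment"`: `haplotype_strain`
#'   (haplotype, strain), `individual_strain` (individual_id, strain),
#'   `strains` (strain, component, n_haplotypes, n_individuals, major).
#' @export
assign_strains <- function(network, individual_haplotypes, min_major = 11) {
  stopifnot(inherits(network, "haplotype_network"),
            all(c("individual_id", "haplotype") %in% names(individual_haplotypes)))
  unmapped <- setdiff(individual_haplotypes$haplotype, network$nodes$label)
  if (length(unmapped) > 0L) {
    stop("haplotype(s) not in network: ", paste(head(unmapped, 5), collapse = ", "))
  }
  comp_of <- network$membership
  ind_comp <- comp_of[individual_haplotypes$haplotype]
  n_by_comp <- table(factor(ind_comp, levels = seq_len(max(comp_of))))
  ord <- order(-as.integer(n_by_comp), as.integer(names(n_by_comp)))
  strain_label <- character(length(n_by_comp))
  strain_label[ord] <- make_strain_labels(length(ord))
  hap_strain <- data.frame(haplotype = network$nodes$label,
                           strain = strain_label[comp_of],
                           stringsAsFactors = FALSE)
  ind_strain <- data.frame(individual_id = individual_haplotypes$individual_id,
                           strain = strain_label[ind_comp],
                           stringsAsFactors = FALSE)
  strains <- data.frame(
    strain = strain_label[ord],
    component = as.integer(names(n_by_comp))[ord],
    n_haplotypes = as.integer(table(factor(comp_of, levels = seq_len(max(comp_of)))))[ord],
    n_individuals = as.integer(n_by_comp)[ord],
    stringsAsFactors = FALSE)
  strains$major <- strains$n_individuals >= min_major
  out <- list(haplotype_strain = hap_strain, individual_strain = ind_strain,
              strains = strains, min_major = min_major)
  class(out) <- "strain_assignment"
  out
}

make_strain_labels <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)]
  else c(LETTERS, paste0("Z", seq_len(n - 26)))[seq_len(n)]
}

#' @export
print.strain_assignment <- function(x, ...) {
  cat("strain_assignment:\n")
  print(x$strains)
  invisible(x)
}

#' Per-strain haplotype frequency spectrum
#'
#' @param assignment a [assign_strains()] result.
#' @param individual_haplotypes the same individual-to-haplotype map used for
#'   the assignment.
#' @return data.frame: `strain`, `n_haplotypes`, `n_individuals`,
#'   `multiplicities` (comma-joined, decreasing).
#' @export
haplotype_spectrum <- function(assignment, individual_haplotypes) {
  stopifnot(inherits(assignment, "strain_assignment"))
  hs <- assignment$haplotype_strain
  tab <- table(individual_haplotypes$haplotype)
  out <- do.call(rbind, lapply(assignment$strains$strain, function(s) {
    haps <- hs$haplotype[hs$strain == s]
    mult <- sort(as.integer(tab[haps]), decreasing = TRUE)
    mult <- mult[!is.na(mult)]
    data.frame(strain = s, n_haplotypes = length(haps),
               n_individuals = sum(mult),
               multiplicities = paste(mult, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
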