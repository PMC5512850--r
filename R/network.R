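#' Bipartite mutualistic network
#'
#' Constructs a `bipartite_network` from a binary incidence matrix with plant
#' species as rows and animal species as columns. The incidence matrix `a[i, k]`
#' is 1 when plant `i` and animal `k` interact (e.g. a pollination record) and 0
#' otherwise.
#'
#' @param incidence Binary matrix (plants x animals). Any positive entry is
#'   treated as a link; entries must be non-negative and finite.
#' @param plants,animals Optional character vectors of species labels. Default
#'   labels `P1...`/`A1...` are generated.
#' @param allow_empty If `FALSE` (default), species without any link are
#'   rejected: every row and column must contain at least one 1. Set `TRUE` to
#'   keep them (descriptors then treat them as degree-0 species).
#'
#' @return An object of class `bipartite_network`: a list with elements
#'   `incidence` (integer matrix), `plants`, `animals`.
#' @examples
#' net <- bipartite_network(matrix(c(1, 1, 0, 1), 2, 2))
#' connectance(net)
#' @export
bipartite_network <- function(incidence, plants = NULL, animals = NULL,
                              allow_empty = FALSE) {
  incidence <- as.matrix(incidence)
  if (nrow(incidence) < 2L || ncol(incidence) < 2L) {
    abort_domain("a bipartite network needs at least 2 plants and 2 animals")
  }
  if (!is.numeric(incidence) || anyNA(incidence) || any(incidence < 0) ||
      any(!is.finite(incidence))) {
    abort_domain("incidence entries must be finite and non-negative")
  }
  if (any(incidence > 0 & incidence != 1)) {
    warning("non-binary positive entries coerced to presence (1)", call. = FALSE)
  }
  inc <- matrix(as.integer(incidence > 0), nrow(incidence), ncol(incidence))
  if (!allow_empty && (any(rowSums(inc) == 0L) || any(colSums(inc) == 0L))) {
    abort_domain("network has species without links (set allow_empty = TRUE to keep them)")
  }
  rownames(inc) <- plants %||% paste0("P", seq_len(nrow(inc)))
  colnames(inc) <- animals %||% paste0("A", seq_len(ncol(inc)))
  structure(list(incidence = inc,
                 plants = rownames(inc),
                 animals = colnames(inc)),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network> %d plants x %d animals, %d links (kappa = %.3f)\n",
              n_plants(x), n_animals(x), n_links(x), connectance(x)))
  invisible(x)
}

is_bipartite_network <- function(x) inherits(x, "bipartite_network")

as_network <- function(x) {
  if (is_bipartite_network(x)) return(x)
  if (is.matrix(x)) return(bipartite_network(x))
  abort_domain("expected a bipartite_network or an incidence matrix")
}

#' @rdname network-descriptors
#' @export
n_plants <- function(net) nrow(as_network(net)$incidence)

#' @rdname network-descriptors
#' @export
n_animals <- function(net) ncol(as_network(net)$incidence)

#' @rdname network-descriptors
#' @export
n_links <- function(net) sum(as_network(net)$incidence)

#' Network descriptors
#'
#' Degree vectors, connectance, nestedness and degree-distribution moments of a
#' bipartite network.
#'
#' `connectance()` is the fraction of realized links,
#' \eqn{\kappa = L / (S^{(P)} S^{(A)})}, identical to the mean plant degree over
#' the number of animals and to the mean animal degree over the number of
#' plants.
#'
#' `nestedness()` is the shared-partner measure: for a guild with degrees
#' \eqn{d_i} and pairwise common-partner counts \eqn{n_{ij}},
#' \deqn{\nu = \langle n_{ij} / \min(d_i, d_j) \rangle_{i<j},}
#' the average over same-guild species pairs of the fraction of the links of the
#' more specialist species that are shared with the more generalist one. It
#' equals 1 for a fully connected network and 0 for a perfect matching, and —
#' unlike the ratio-of-sums variant, which is fully determined by the two degree
#' sequences — it responds to degree-preserving link rewiring, which is what
#' makes the Metropolis tuner ([tune_nestedness()]) possible. `guild = "both"`
#' averages over the pairs of both guilds; this pooled value is what the tuner
#' targets.
#'
#' @param net A [bipartite_network()] (or incidence matrix).
#' @param guild `"plants"`, `"animals"`, or `"both"` (pooled).
#' @return `connectance()`/`nestedness()` return a scalar; `degrees()` an
#'   integer vector; `glance()` a one-row tibble of all descriptors.
#' @name network-descriptors
NULL

#' @rdname network-descriptors
#' @export
degrees <- function(net, guild = c("plants", "animals")) {
  net <- as_network(net)
  switch(match.arg(guild),
         plants = as.integer(rowSums(net$incidence)),
         animals = as.integer(colSums(net$incidence)))
}

#' @rdname network-descriptors
#' @export
connectance <- function(net) {
  net <- as_network(net)
  L <- n_links(net)
  if (L == 0L) abort_domain("empty network: connectance undefined")
  L / (n_plants(net) * n_animals(net))
}

#' @rdname network-descriptors
#' @export
degree_ratio <- function(net, guild = c("plants", "animals")) {
  d <- degrees(net, match.arg(guild))
  mean(d^2) / mean(d)
}

shared_links <- function(inc, guild) {
  # per-pair shared-link fractions n_ij / min(d_i, d_j) for one guild;
  # pairs of two degree-0 species are skipped (undefined fraction)
  m <- if (guild == "plants") inc else t(inc)
  d <- rowSums(m)
  common <- tcrossprod(m)            # n_ij in off-diagonal
  pairs <- upper.tri(common)
  mins <- outer(d, d, pmin)
  keep <- pairs & mins > 0
  list(sum = sum(common[keep] / mins[keep]), n_pairs = sum(keep))
}

#' @rdname network-descriptors
#' @export
nestedness <- function(net, guild = c("plants", "animals", "both")) {
  net <- as_network(net)
  guild <- match.arg(guild)
  inc <- net$incidence
  parts <- switch(guild,
                  plants = list(shared_links(inc, "plants")),
                  animals = list(shared_links(inc, "animals")),
                  both = list(shared_links(inc, "plants"),
                              shared_links(inc, "animals")))
  num <- sum(vapply(parts, `[[`, numeric(1), "sum"))
  den <- sum(vapply(parts, `[[`, numeric(1), "n_pairs"))
  if (den == 0) abort_domain("all pairwise minimum degrees are zero: nestedness undefined")
  num / den
}

#' @rdname network-descriptors
#' @export
glance.bipartite_network <- function(x, ...) {
  tibble::tibble(
    n_plants = n_plants(x),
    n_animals = n_animals(x),
    links = n_links(x),
    connectance = connectance(x),
    nestedness = nestedness(x, "both"),
    nestedness_plants = nestedness(x, "plants"),
    nestedness_animals = nestedness(x, "animals"),
    degree_ratio_plants = degree_ratio(x, "plants"),
    degree_ratio_animals = degree_ratio(x, "animals")
  )
}

#' Read / write binary incidence matrices
#'
#' Plain-CSV dialect for bipartite incidence matrices in the Web-of-Life style:
#' plants as rows, animals as columns, optional header row and first label
#' column. Quantitative entries (visit counts) are binarized with a warning.
#'
#' @param path File path.
#' @param net A [bipartite_network()].
#' @return `read_incidence()` returns a `bipartite_network`;
#'   `write_incidence()` returns `path` invisibly. A written file read back
#'   yields an identical incidence matrix.
#' @export
read_incidence <- function(path) {
  if (!file.exists(path)) abort_domain(sprintf("file not found: %s", path))
  raw <- tryCatch(utils::read.csv(path, check.names = FALSE,
                                  stringsAsFactors = FALSE),
                  error = function(e) abort_domain(
                    sprintf("malformed incidence CSV (%s)", conditionMessage(e)),
                    class = "mutualstab_format_error"))
  if (nrow(raw) == 0L || ncol(raw) == 0L) {
    abort_domain("empty incidence file", class = "mutualstab_format_error")
  }
  plants <- NULL
  if (!is.numeric(raw[[1]]) || anyNA(suppressWarnings(as.numeric(raw[[1]])))) {
    plants <- as.character(raw[[1]])
    raw <- raw[, -1, drop = FALSE]
  }
  m <- as.matrix(raw)
  storage.mode(m) <- "numeric"
  if (anyNA(m) || any(m < 0)) {
    abort_domain("incidence entries must be numeric and non-negative",
                 class = "mutualstab_format_error")
  }
  bipartite_network(m, plants = plants, animals = colnames(raw))
}

#' @rdname read_incidence
#' @export
write_incidence <- function(net, path) {
  net <- as_network(net)
  df <- as.data.frame(net$incidence)
  utils::write.csv(cbind(species = net$plants, df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Incidence heat-tile plot of a bipartite network
#'
#' @param object A [bipartite_network()].
#' @param sort Order species by decreasing degree (the conventional nested
#'   layout)? Default `TRUE`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.bipartite_network <- function(object, sort = TRUE, ...) {
  inc <- object$incidence
  if (sort) {
    inc <- inc[order(rowSums(inc), decreasing = TRUE),
               order(colSums(inc), decreasing = TRUE), drop = FALSE]
  }
  df <- tibble::tibble(
    plant = factor(rep(rownames(inc), ncol(inc)), levels = rev(rownames(inc))),
    animal = factor(rep(colnames(inc), each = nrow(inc)), levels = colnames(inc)),
    link = as.vector(inc) == 1L
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$animal, y = .data$plant,
                                   fill = .data$link)) +
    ggplot2::geom_tile(colour = "grey85", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey15", `FALSE` = "white"),
                               guide = "none") +
    ggplot2::labs(x = "animals", y = "plants") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
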