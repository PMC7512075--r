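#' Place neurons and astrocytes in the 2D domain
#'
#' Neurons are placed uniformly at random in the square domain; astrocytes sit
#' on a regular centred \code{sqrt(n_astro) x sqrt(n_astro)} lattice (for the
#' defaults: 20 x 20 at 0.5-mm pitch). Lattice placement gives each interior
#' astrocyte exactly four neighbours under the default 675-um coupling radius.
#' Both placement schemes are available for either cell class.
#'
#' @param n_exc,n_inh numbers of excitatory / inhibitory neurons
#' @param n_astro number of astrocytes; must be a perfect square for lattice
#'   placement
#' @param domain_size side length of the square domain (mm)
#' @param seed integer RNG seed (layout construction is fully seeded)
#' @param neuron_placement \code{"random"} (default) or \code{"lattice"}
#' @param astro_placement \code{"lattice"} (default) or \code{"random"}
#' @return a list with \code{neuron_pos} (matrix, mm), \code{neuron_type}
#'   (character, "E"/"I"), \code{astro_pos} (matrix, mm)
#' @export
place_cells <- function(n_exc = 400, n_inh = 100, n_astro = 400,
                        domain_size = 10, seed = 1,
                        neuron_placement = c("random", "lattice"),
                        astro_placement = c("lattice", "random")) {
  stopifnot(n_exc > 0, n_inh > 0, n_astro > 0, domain_size > 0)
  neuron_placement <- match.arg(neuron_placement)
  astro_placement <- match.arg(astro_placement)
  n_neu <- n_exc + n_inh
  lattice <- function(n) {
    side <- sqrt(n)
    if (side != floor(side)) {
      stop("lattice placement needs a perfect-square cell count")
    }
    pitch <- domain_size / side
    xy <- (seq_len(side) - 0.5) * pitch
    as.matrix(expand.grid(x = xy, y = xy))
  }
  rng <- local({
    set.seed(seed)
    function(n) matrix(stats::runif(2 * n, 0, domain_size), ncol = 2,
                       dimnames = list(NULL, c("x", "y")))
  })
  neuron_pos <- if (neuron_placement == "random") rng(n_neu) else
    lattice(n_neu)
  astro_pos <- if (astro_placement == "random") rng(n_astro) else
    lattice(n_astro)
  list(neuron_pos = neuron_pos,
       neuron_type = c(rep("E", n_exc), rep("I", n_inh)),
       astro_pos = astro_pos)
}

#' Draw the neuron-to-neuron synapse list
#'
#' Every ordered pair of distinct neurons is connected independently with
#' probability \code{p}; the synapse type is the presynaptic neuron's type.
#'
#' @param types character vector of neuron types ("E"/"I")
#' @param p connection probability in [0, 1]
#' @param seed integer RNG seed
#' @return a data.frame with columns \code{pre}, \code{post} (1-based ids)
#'   and \code{type}
#' @export
connect_neurons <- function(types, p = 0.2, seed = 1) {
  stopifnot(p >= 0, p <= 1)
  n <- length(types)
  set.seed(seed)
  draw <- matrix(stats::runif(n * n) < p, n, n)
  diag(draw) <- FALSE
  idx <- which(draw, arr.ind = TRUE)
  # row = pre, col = post; order by (pre, post) for a deterministic table
  o <- order(idx[, 1], idx[, 2])
  data.frame(pre = idx[o, 1], post = idx[o, 2],
             type = types[idx[o, 1]], stringsAsFactors = FALSE)
}

#' Assign excitatory synapses to their nearest astrocyte
#'
#' Each excitatory synapse is represented by the midpoint of its pre- and
#' postsynaptic somata and assigned to the astrocyte minimising the Euclidean
#' distance to that point (ties broken by the lowest astrocyte id).
#' Inhibitory synapses are left unassigned (NA).
#'
#' @param synapses synapse table from \code{\link{connect_neurons}}
#' @param neuron_pos neuron position matrix (mm)
#' @param astro_pos astrocyte position matrix (mm)
#' @param site \code{"midpoint"} (default) or \code{"min_soma"}: take the
#'   synapse-astrocyte distance from the soma midpoint, or as the minimum over
#'   the two somata
#' @return an integer vector, one entry per synapse: the 1-based astrocyte id
#'   for excitatory synapses, NA for inhibitory ones
#' @export
assign_synapses_to_astrocytes <- function(synapses, neuron_pos, astro_pos,
                                          site = c("midpoint", "min_soma")) {
  site <- match.arg(site)
  out <- rep(NA_integer_, nrow(synapses))
  exc <- which(synapses$type == "E")
  if (length(exc) == 0) return(out)
  ax <- astro_pos[, 1]; ay <- astro_pos[, 2]
  nearest <- function(px, py) {
    # chunked distance scan; which.min takes the first (lowest-id) minimum
    res <- integer(length(px))
    for (s in seq(1, length(px), by = 4096)) {
      e <- min(s + 4095, length(px))
      d2 <- outer(px[s:e], ax, "-")^2 + outer(py[s:e], ay, "-")^2
      res[s:e] <- max.col(-d2, ties.method = "first")
    }
    res
  }
  p1 <- neuron_pos[synapses$pre[exc], , drop = FALSE]
  p2 <- neuron_pos[synapses$post[exc], , drop = FALSE]
  if (site == "midpoint") {
    out[exc] <- nearest((p1[, 1] + p2[, 1]) / 2, (p1[, 2] + p2[, 2]) / 2)
  } else {
    d2a <- outer(p1[, 1], ax, "-")^2 + outer(p1[, 2], ay, "-")^2
    d2b <- outer(p2[, 1], ax, "-")^2 + outer(p2[, 2], ay, "-")^2
    out[exc] <- max.col(-pmin(d2a, d2b), ties.method = "first")
  }
  out
}

#' Build the astrocyte gap-junction graph
#'
#' Undirected edge between every astrocyte pair closer than \code{radius}
#' (default 675 um, matching the mean astrocyte intersomal distance); on the
#' default 0.5-mm lattice this couples each interior astrocyte to its four
#' axial neighbours (diagonals at ~707 um are excluded).
#'
#' @param astro_pos astrocyte position matrix (mm)
#' @param radius coupling radius (mm)
#' @return a two-column matrix of 1-based astrocyte id pairs (i < j)
#' @export
connect_astrocytes <- function(astro_pos, radius = 0.675) {
  stopifnot(radius > 0)
  d <- as.matrix(stats::dist(astro_pos))
  d[lower.tri(d, diag = TRUE)] <- Inf
  idx <- which(d <= radius, arr.ind = TRUE)
  o <- order(idx[, 1], idx[, 2])
  m <- cbind(i = idx[o, 1], j = idx[o, 2])
  rownames(m) <- NULL
  m
}

#' Build the full spatial neuron-astrocyte network
#'
#' Seeded construction of the complete layout: cell placement, Bernoulli
#' neuron connectivity, nearest-astrocyte territory assignment of excitatory
#' synapses, and the astrocyte gap-junction graph. Identical seeds give
#' identical layouts.
#'
#' @inheritParams place_cells
#' @param p neuron connection probability
#' @param astro_radius gap-junction coupling radius (mm)
#' @param assignment_site see \code{\link{assign_synapses_to_astrocytes}}
#' @return an object of class \code{network_layout}: a list with
#'   \code{neuron_pos}, \code{neuron_type}, \code{astro_pos}, \code{synapses}
#'   (with \code{astro} column), \code{astro_edges}, \code{domain_size},
#'   \code{seed}
#' @export
#' @examples
#' net <- build_network(n_exc = 40, n_inh = 10, n_astro = 16, seed = 1)
#' net
build_network <- function(n_exc = 400, n_inh = 100, n_astro = 400,
                          p = 0.2, domain_size = 10, seed = 1,
                          astro_radius = 0.675,
                          neuron_placement = c("random", "lattice"),
                          astro_placement = c("lattice", "random"),
                          assignment_site = c("midpoint", "min_soma")) {
  cells <- place_cells(n_exc, n_inh, n_astro, domain_size, seed,
                       match.arg(neuron_placement),
                       match.arg(astro_placement))
  syn <- connect_neurons(cells$neuron_type, p, seed = seed + 1L)
  syn$astro <- assign_synapses_to_astrocytes(syn, cells$neuron_pos,
                                             cells$astro_pos,
                                             match.arg(assignment_site))
  edges <- connect_astrocytes(cells$astro_pos, astro_radius)
  structure(list(neuron_pos = cells$neuron_pos,
                 neuron_type = cells$neuron_type,
                 astro_pos = cells$astro_pos,
                 synapses = syn, astro_edges = edges,
                 domain_size = domain_size, seed = seed),
            class = "network_layout")
}

#' @export
print.network_layout <- function(x, ...) {
  n_e <- sum(x$neuron_type == "E"); n_i <- sum(x$neuron_type == "I")
  n_es <- sum(x$synapses$type == "E")
  cat("<network_layout>\n",
      " neurons:    ", n_e, "E +", n_i, "I in",
      paste0(x$domain_size, "x", x$domain_size, " mm\n"),
      " astrocytes: ", nrow(x$astro_pos), "\n",
      " synapses:   ", nrow(x$synapses),
      paste0("(", n_es, " excitatory; mean ",
             round(n_es / nrow(x$astro_pos), 1), " per astrocyte)\n"),
      " gap edges:  ", nrow(x$astro_edges),
      paste0("(mean degree ",
             round(2 * nrow(x$astro_edges) / nrow(x$astro_pos), 2), ")\n"),
      " seed:       ", x$seed, "\n")
  invisible(x)
}

#' Serialize / restore a network layout
#'
#' Writes the layout (positions, types, synapse and edge tables, seed) as
#' JSON so a run can be reproduced without re-deriving the layout; the
#' round trip is exact.
#'
#' @param layout a \code{network_layout} object
#' @param path file path
#' @return \code{write_layout}: \code{path}, invisibly. \code{read_layout}:
#'   the restored \code{network_layout}.
#' @export
write_layout <- function(layout, path) {
  obj <- list(neuron_pos = unclass(layout$neuron_pos),
              neuron_type = layout$neuron_type,
              astro_pos = unclass(layout$astro_pos),
              synapses = layout$synapses,
              astro_edges = unclass(layout$astro_edges),
              domain_size = layout$domain_size,
              seed = layout$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- as.data.frame(obj$synapses, stringsAsFactors = FALSE)
  syn$astro <- as.integer(syn$astro)
  structure(list(neuron_pos = matrix(unlist(obj$neuron_pos), ncol = 2,
                                     dimnames = list(NULL, c("x", "y"))),
                 neuron_type = obj$neuron_type,
                 astro_pos = matrix(unlist(obj$astro_pos), ncol = 2,
                                    dimnames = list(NULL, c("x", "y"))),
                 synapses = syn,
                 astro_edges = matrix(as.integer(unlist(obj$astro_edges)),
                                      ncol = 2,
                                      dimnames = list(NULL, c("i", "j"))),
                 domain_size = obj$domain_size,
                 seed = as.integer(obj$seed)),
            class = "network_layout")
}
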