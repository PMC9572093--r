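#' Atom label for substructural descriptors
#'
#' The label is the element symbol, prefixed with `-` when the atom is acyclic,
#' with a non-zero formal charge appended as `+`/`-` repeated `|charge|` times.
#' Ring membership must already be perceived.
#'
#' @param g a [molecular_graph()].
#' @return Character vector of per-atom labels.
#' @examples
#' \donttest{
#' atom_labels(parse_structures("CO methanol", "smiles")[[1]])
#' }
#' @export
atom_labels <- function(g) {
  lab <- ifelse(g$in_ring, g$element, paste0("-", g$element))
  chg <- g$charge
  dec <- ifelse(chg > 0, strrep("+", chg), strrep("-", -pmin(chg, 0L)))
  paste0(lab, dec)
}

#' Multilevel neighborhood-of-atoms (MNA) descriptors
#'
#' Generates the recursive substructural descriptors: the level-0 descriptor of
#' an atom is its label; the level-k descriptor is
#' `label(atom)(D1 D2 ...)` where `Di` are the level-(k-1) descriptors of the
#' immediate neighbors, concatenated in lexicographic (byte) order so that the
#' text is canonical. One descriptor is emitted per atom per level 0..max_level
#' and the result is the multiset of all of them.
#'
#' @param g a [molecular_graph()] (ring flags set).
#' @param max_level highest neighborhood level, >= 0 (default 2).
#' @param include_h if `FALSE`, hydrogen atoms are removed from the graph
#'   before generation (they then appear neither as centers nor as neighbors).
#' @return Named integer vector: descriptor text -> occurrence count. The
#'   level of each descriptor is recoverable from its nesting depth.
#' @examples
#' \donttest{
#' mna_descriptors(parse_structures("C methane", "smiles")[[1]], max_level = 1)
#' }
#' @export
mna_descriptors <- function(g, max_level = 2L, include_h = TRUE) {
  if (max_level < 0L) stop("max_level must be >= 0")
  if (!include_h) g <- drop_hydrogens(g)
  n <- n_atoms(g)
  nbr <- neighbor_list(g)
  lab <- atom_labels(g)
  # level-k text = plain atom mark + "(" + sorted level-(k-1) neighbor texts + ")"
  cur <- lab
  all_desc <- cur
  lev <- 0L
  while (lev < max_level) {
    nxt <- vapply(seq_len(n), function(i) {
      ds <- cur[nbr[[i]]]
      paste0(lab[i], "(", paste(sort(ds, method = "radix"), collapse = ""), ")")
    }, "")
    all_desc <- c(all_desc, nxt)
    cur <- nxt
    lev <- lev + 1L
  }
  counts <- table(all_desc)
  stats::setNames(as.integer(counts), names(counts))
}

# neighbor index list from the bond matrix
neighbor_list <- function(g) {
  n <- n_atoms(g)
  nbr <- vector("list", n)
  b <- g$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      i <- b[k, 1L]; j <- b[k, 2L]
      nbr[[i]] <- c(nbr[[i]], j)
      nbr[[j]] <- c(nbr[[j]], i)
    }
  }
  nbr
}

# remove hydrogen atoms, remapping bonds
drop_hydrogens <- function(g) {
  keep <- g$element != "H"
  if (all(keep)) return(g)
  map <- cumsum(keep)
  b <- g$bonds
  b <- b[keep[b[, 1L]] & keep[b[, 2L]], , drop = FALSE]
  b <- cbind(map[b[, 1L]], map[b[, 2L]])
  g2 <- molecular_graph(g$element[keep], b, g$charge[keep], id = g$id)
  g2
}

#' Whole-molecule descriptors
#'
#' Three scalar descriptors accompany the substructural counts, all computed
#' on the heavy-atom (hydrogen-suppressed) graph:
#' \describe{
#'   \item{`topological_length`}{graph diameter in bonds — the maximum over
#'     atom pairs of the shortest-path length. On a disconnected graph the
#'     largest component is used, with a warning.}
#'   \item{`topological_volume`}{sum of per-element additive contributions
#'     (default table: van-der-Waals-like relative volumes).}
#'   \item{`lipophilicity`}{additive atomic-contribution log P estimate
#'     (default table: published-style per-element fragment increments).}
#' }
#' Both contribution tables are pluggable named numeric vectors; an element
#' missing from the supplied table is an error naming the element.
#'
#' @param g a [molecular_graph()].
#' @param contributions,scheme named numeric vector: element -> contribution.
#' @return A single number.
#' @name whole_molecule
NULL

#' @rdname whole_molecule
#' @export
topological_length <- function(g) {
  h <- drop_hydrogens(g)
  if (n_atoms(h) == 1L) return(0L)
  ig <- igraph::graph_from_edgelist(h$bonds, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, n_atoms(h) - igraph::vcount(ig)))
  comp <- igraph::components(ig)
  if (comp$no > 1L) {
    warning("disconnected heavy-atom graph; topological length computed on largest component")
    big <- which.max(comp$csize)
    ig <- igraph::induced_subgraph(ig, which(comp$membership == big))
  }
  d <- igraph::distances(ig)
  as.integer(max(d[is.finite(d)]))
}

#' @rdname whole_molecule
#' @export
topological_volume <- function(g, contributions = default_volume_table()) {
  h <- drop_hydrogens(g)
  miss <- setdiff(unique(h$element), names(contributions))
  if (length(miss))
    stop("no volume contribution for element(s): ", paste(miss, collapse = ", "))
  sum(contributions[h$element])
}

#' @rdname whole_molecule
#' @export
lipophilicity <- function(g, scheme = default_logp_table()) {
  miss <- setdiff(unique(g$element), names(scheme))
  if (length(miss))
    stop("no lipophilicity contribution for element(s): ", paste(miss, collapse = ", "))
  sum(scheme[g$element])
}

#' @rdname whole_molecule
#' @export
default_volume_table <- function() {
  # relative van-der-Waals volumes (A^3-like additive units, heavy atoms)
  c(C = 20.6, N = 15.6, O = 14.7, S = 24.4, P = 24.9,
    F = 13.3, Cl = 22.4, Br = 26.5, I = 32.5, B = 18.3, Si = 38.8)
}

#' @rdname whole_molecule
#' @export
default_logp_table <- function() {
  # crude per-element additive logP increments; H carries a small positive
  # share so CH2 insertion under this scheme increases lipophilicity
  c(C = 0.36, H = 0.12, N = -0.60, O = -0.40, S = 0.26, P = -0.45,
    F = 0.22, Cl = 0.65, Br = 0.85, I = 1.10, B = 0.0, Si = 0.4)
}

#' Per-compound descriptor vector
#'
#' Bundles the MNA multiset with the three whole-molecule descriptors.
#'
#' @param g a [molecular_graph()].
#' @param max_level,include_h passed to [mna_descriptors()].
#' @param family `"mna"` for substructural counts or `"ana"` for the numeric
#'   atom-neighborhood-aggregate family (see [ana_descriptors()]).
#' @return A list of class `descriptor_vector` with `counts` (named numeric),
#'   `topo_length`, `topo_volume`, `lipophilicity`, and `id`.
#' @export
descriptor_vector <- function(g, max_level = 2L, include_h = TRUE,
                              family = c("mna", "ana")) {
  family <- match.arg(family)
  counts <- if (family == "mna")
    mna_descriptors(g, max_level = max_level, include_h = include_h)
  else ana_descriptors(g)
  structure(list(id = g$id, counts = counts,
                 topo_length = topological_length(g),
                 topo_volume = topological_volume(g),
                 lipophilicity = lipophilicity(g),
                 family = family, level = max_level),
            class = "descriptor_vector")
}

#' Numeric atom-neighborhood-aggregate descriptors
#'
#' A compact numeric descriptor family of this package's own design, used as a
#' second, structurally different family alongside the MNA counts when
#' building diverse consensus ensembles. For every element present, four
#' aggregates over the atoms of that element are emitted: atom count, total
#' heavy-neighbor degree, ring-atom count, and total attached-hydrogen count.
#'
#' @param g a [molecular_graph()].
#' @return Named numeric vector with keys like `ana:C:count`.
#' @export
ana_descriptors <- function(g) {
  nbr <- neighbor_list(g)
  heavy <- g$element != "H"
  out <- numeric(0)
  for (el in sort(unique(g$element[heavy]), method = "radix")) {
    idx <- which(g$element == el)
    hdeg <- vapply(nbr[idx], function(v) sum(g$element[v] != "H"), 0L)
    nh <- vapply(nbr[idx], function(v) sum(g$element[v] == "H"), 0L)
    out[paste0("ana:", el, ":count")] <- length(idx)
    out[paste0("ana:", el, ":hdeg")] <- sum(hdeg)
    out[paste0("ana:", el, ":ring")] <- sum(g$in_ring[idx])
    out[paste0("ana:", el, ":nh")] <- sum(nh)
  }
  out
}

# column names reserved for the three whole-molecule descriptors
WHOLE_MOL_COLS <- c("topo_length", "topo_volume", "lipophilicity")

#' Assemble a dataset descriptor matrix
#'
#' Training mode (no `vocabulary`): the vocabulary is the union of observed
#' descriptor keys in first-seen then lexicographic order. Prediction mode
#' (`vocabulary` supplied): columns follow the given vocabulary exactly;
#' descriptors of a compound that are absent from the vocabulary are dropped,
#' and their per-compound fraction is reported in the `unseen_fraction`
#' attribute (consumed by the applicability domain). The three whole-molecule
#' descriptors occupy fixed trailing columns.
#'
#' @param vectors list of [descriptor_vector()] objects.
#' @param vocabulary optional ordered character vector of descriptor keys
#'   (without the whole-molecule columns).
#' @return Numeric matrix (ids x columns) with attributes `vocabulary` and
#'   `unseen_fraction`.
#' @export
build_matrix <- function(vectors, vocabulary = NULL) {
  if (!length(vectors)) stop("empty descriptor vector list")
  keysets <- lapply(vectors, function(v) names(v$counts))
  if (is.null(vocabulary)) {
    seen <- character(0)
    for (ks in keysets) {
      new <- setdiff(ks, seen)
      seen <- c(seen, sort(new, method = "radix"))
    }
    vocabulary <- seen
  }
  n <- length(vectors)
  p <- length(vocabulary)
  m <- matrix(0, nrow = n, ncol = p + 3L,
              dimnames = list(vapply(vectors, `[[`, "", "id"),
                              c(vocabulary, WHOLE_MOL_COLS)))
  unseen <- numeric(n)
  for (i in seq_len(n)) {
    v <- vectors[[i]]
    hit <- names(v$counts) %in% vocabulary
    unseen[i] <- if (length(v$counts)) sum(!hit) / length(v$counts) else 0
    if (any(hit)) m[i, names(v$counts)[hit]] <- v$counts[hit]
    m[i, WHOLE_MOL_COLS] <- c(v$topo_length, v$topo_volume, v$lipophilicity)
  }
  if (any(unseen > 0))
    message(sum(unseen > 0), " compound(s) carry descriptors absent from the vocabulary")
  attr(m, "vocabulary") <- vocabulary
  attr(m, "unseen_fraction") <- stats::setNames(unseen, rownames(m))
  m
}

#' Descriptor matrix for a set of structures
#'
#' Convenience wrapper: [descriptor_vector()] per graph, then [build_matrix()].
#'
#' @param graphs list of [molecular_graph()] objects.
#' @inheritParams descriptor_vector
#' @inheritParams build_matrix
#' @export
descriptor_matrix <- function(graphs, max_level = 2L, include_h = TRUE,
                              family = "mna", vocabulary = NULL) {
  build_matrix(lapply(graphs, descriptor_vector, max_level = max_level,
                      include_h = include_h, family = family),
               vocabulary = vocabulary)
}
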