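#' Hydrogen-explicit molecular graphs
#'
#' A `molecular_graph` is the substrate for descriptor generation: a list of
#' atoms (element symbol, formal charge, ring flag) plus an undirected bond
#' list over 1-based atom indices. Hydrogens are always explicit atoms; bond
#' orders are parsed but deliberately not stored, since the descriptor
#' machinery ignores bond types.
#'
#' @param elements character vector of element symbols.
#' @param bonds two-column integer matrix of bonded atom-index pairs
#'   (unordered; no self-bonds).
#' @param charges integer vector of formal charges (recycled scalar allowed).
#' @param id single character identifier.
#' @return An object of class `molecular_graph` with components `id`,
#'   `element`, `charge`, `in_ring` (logical, set by [perceive_rings()]) and
#'   `bonds`.
#' @examples
#' g <- molecular_graph(c("C", "H", "H", "H", "H"),
#'                      cbind(1L, 2:5), id = "methane")
#' n_atoms(g)
#' @export
molecular_graph <- function(elements, bonds, charges = 0L, id = "") {
  stopifnot(is.character(elements), length(elements) >= 1L)
  if (is.null(bonds) || length(bonds) == 0L) {
    bonds <- matrix(integer(0), ncol = 2L)
  }
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  n <- length(elements)
  if (nrow(bonds) > 0L) {
    if (any(bonds < 1L | bonds > n))
      stop("bond endpoint outside atom index range 1..", n)
    if (any(bonds[, 1L] == bonds[, 2L]))
      stop("self-bonds are not allowed")
    # canonical order: low index first, rows sorted
    bonds <- cbind(pmin(bonds[, 1L], bonds[, 2L]),
                   pmax(bonds[, 1L], bonds[, 2L]))
    bonds <- unique(bonds[order(bonds[, 1L], bonds[, 2L]), , drop = FALSE])
  }
  charges <- rep_len(as.integer(charges), n)
  g <- structure(
    list(id = as.character(id), element = elements, charge = charges,
         in_ring = rep(FALSE, n), bonds = bonds),
    class = "molecular_graph")
  perceive_rings(g)
}

#' @rdname molecular_graph
#' @param g a `molecular_graph`.
#' @export
n_atoms <- function(g) length(g$element)

#' @export
print.molecular_graph <- function(x, ...) {
  tab <- table(x$element)
  cat(sprintf("molecular_graph '%s': %d atoms (%s), %d bonds, %d ring atoms\n",
              x$id, n_atoms(x),
              paste(names(tab), tab, sep = ":", collapse = " "),
              nrow(x$bonds), sum(x$in_ring)))
  invisible(x)
}

#' Flag atoms lying on a ring
#'
#' Sets `in_ring` to `TRUE` exactly for atoms that lie on at least one simple
#' cycle. An edge lies on a cycle iff it is not a bridge of the graph, so ring
#' atoms are the endpoints of non-bridge edges (computed with igraph).
#'
#' @param g a `molecular_graph`.
#' @return The graph with its `in_ring` field recomputed.
#' @export
perceive_rings <- function(g) {
  n <- n_atoms(g)
  g$in_ring <- rep(FALSE, n)
  if (nrow(g$bonds) == 0L) return(g)
  ig <- igraph::graph_from_edgelist(g$bonds, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, n - igraph::vcount(ig)))
  br <- igraph::bridges(ig)
  cyc_edges <- setdiff(seq_len(nrow(g$bonds)), as.integer(br))
  if (length(cyc_edges))
    g$in_ring[unique(as.vector(g$bonds[cyc_edges, , drop = FALSE]))] <- TRUE
  g
}

# Convert one ChemmineR SDF object (hydrogens already explicit) to a
# molecular_graph. The legacy V2000 per-atom charge field is decoded
# (1..3 -> +3..+1, 5..7 -> -1..-3, 0/4 -> 0).
sdf_to_graph <- function(sdf, id = "") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  charges <- integer(length(elements))
  if ("C6" %in% colnames(ab)) {
    raw <- as.integer(ab[, "C6"])
    charges <- ifelse(raw %in% 1:3, 4L - raw,
                      ifelse(raw %in% 5:7, 4L - raw, 0L))
  }
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) NULL else
    cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]))
  molecular_graph(elements, bonds, charges, id = id)
}

#' Read molecular structures as hydrogen-explicit graphs
#'
#' Parses a SMILES flat file (one record per line:
#' `structure [whitespace id [whitespace activity]]`) or an SDF V2000 file.
#' Conversion and hydrogen normalization are delegated to OpenBabel (via
#' ChemmineOB): implicit hydrogens are made explicit before graph extraction,
#' and aromatic rings are kekulized, which is immaterial downstream because
#' bond orders are discarded. Record order and ids are preserved; SMILES
#' records without an id get `mol<line>`.
#'
#' @param source path to a file, or a character vector of lines (SMILES) /
#'   the file text (SDF).
#' @param format `"smiles"` or `"sdf"`.
#' @return A named list of [molecular_graph()] objects, with an `activity`
#'   attribute (numeric vector, `NA` where absent) for SMILES input.
#' @examples
#' \donttest{
#' mols <- parse_structures(c("c1ccccc1 benzene", "CCO ethanol"), "smiles")
#' mols$benzene
#' }
#' @export
parse_structures <- function(source, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else unlist(strsplit(source, "\n", fixed = TRUE))
  if (!length(lines) || all(!nzchar(trimws(lines))))
    stop("empty structure input")

  if (format == "smiles") {
    keep <- nzchar(trimws(lines))
    recs <- strsplit(trimws(lines[keep]), "[ \t]+")
    smi <- vapply(recs, `[[`, "", 1L)
    ids <- vapply(seq_along(recs), function(i)
      if (length(recs[[i]]) >= 2L) recs[[i]][2L] else paste0("mol", i), "")
    act <- vapply(recs, function(r)
      if (length(r) >= 3L) suppressWarnings(as.numeric(r[3L])) else NA_real_, 0)
    src <- paste0(paste(smi, ids), "\n", collapse = "")
    sdf_text <- tryCatch(
      ChemmineOB::convertFormat("SMI", "SDF", src,
                                options = data.frame(names = "h", args = "")),
      error = function(e) stop("SMILES conversion failed: ", conditionMessage(e)))
  } else {
    src <- paste0(paste(lines, collapse = "\n"), "\n")
    ids <- NULL
    act <- NULL
    sdf_text <- tryCatch(
      ChemmineOB::convertFormat("SDF", "SDF", src,
                                options = data.frame(names = "h", args = "")),
      error = function(e) stop("SDF conversion failed: ", conditionMessage(e)))
  }

  sdfset <- ChemmineR::read.SDFset(unlist(strsplit(sdf_text, "\n", fixed = TRUE)))
  ok <- ChemmineR::validSDF(sdfset)
  if (!all(ok))
    stop("unparsable structure at record(s): ", paste(which(!ok), collapse = ", "))
  n <- length(sdfset)
  if (is.null(ids)) {
    ids <- ChemmineR::sdfid(sdfset)
    ids[!nzchar(ids)] <- paste0("mol", which(!nzchar(ids)))
  }
  if (format == "smiles" && n != length(ids))
    stop("unparsable SMILES: ", n, " of ", length(ids), " records converted")
  graphs <- lapply(seq_len(n), function(i) sdf_to_graph(sdfset[[i]], id = ids[i]))
  names(graphs) <- ids
  if (!is.null(act)) attr(graphs, "activity") <- stats::setNames(act, ids)
  graphs
}
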