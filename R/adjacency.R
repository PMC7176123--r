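#' District adjacency graphs
#'
#' An `adjacency_graph` holds the neighbour structure of a set of areal units
#' (health districts). Areas are indexed `1..J` in order of first appearance
#' in the input; the original string codes are carried on every downstream
#' output. The graph must be symmetric, without self-loops or duplicate
#' neighbour entries. Areas with no neighbours ("islands") are permitted but
#' flagged, because the intrinsic CAR conditional is undefined for them; the
#' model fixes an island's structured effect at zero.
#'
#' @param neighbours list of integer vectors, `neighbours[[j]]` the indices of
#'   the areas adjacent to area `j`.
#' @param codes optional character labels, one per area (default `"1".."J"`).
#' @return An object of class `adjacency_graph` with elements `n_areas`,
#'   `neighbours`, `n_neighbours`, `codes`, `islands`.
#' @examples
#' g <- adjacency_graph(list(2L, c(1L, 3L), 2L))
#' g$n_neighbours
#' @export
adjacency_graph <- function(neighbours, codes = NULL) {
  if (!is.list(neighbours) || length(neighbours) == 0L)
    stop("'neighbours' must be a non-empty list of integer vectors")
  J <- length(neighbours)
  neighbours <- lapply(neighbours, function(x) as.integer(x))
  if (is.null(codes)) codes <- as.character(seq_len(J))
  codes <- as.character(codes)
  if (length(codes) != J) stop("'codes' must have one entry per area")
  if (anyDuplicated(codes)) stop("area codes must be unique")

  for (j in seq_len(J)) {
    nb <- neighbours[[j]]
    if (any(is.na(nb)) || any(nb < 1L) || any(nb > J))
      stop(sprintf("neighbour index out of range for area %d", j))
    if (any(nb == j))
      stop(sprintf("self-loop at area %d", j))
    if (anyDuplicated(nb))
      stop(sprintf("duplicate neighbour entry for area %d", j))
    neighbours[[j]] <- sort(nb)
  }
  # symmetry is validated, never silently repaired
  for (j in seq_len(J)) {
    for (l in neighbours[[j]]) {
      if (!(j %in% neighbours[[l]]))
        stop(sprintf(
          "asymmetric adjacency: area %d lists %d but %d does not list %d",
          j, l, l, j))
    }
  }
  m <- vapply(neighbours, length, integer(1))
  islands <- which(m == 0L)
  if (length(islands))
    warning(sprintf("graph contains %d island area(s) (no neighbours): %s",
                    length(islands), paste(codes[islands], collapse = ", ")))
  structure(
    list(n_areas = J, neighbours = neighbours, n_neighbours = m,
         codes = codes, islands = islands),
    class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("adjacency_graph: %d areas, %d edges, %d island(s)\n",
              x$n_areas, sum(x$n_neighbours) %/% 2L, length(x$islands)))
  invisible(x)
}

.graph_from_edges <- function(edges, codes) {
  # edges: 2-column integer matrix, undirected; duplicates of the same
  # undirected pair collapse to one edge
  J <- length(codes)
  if (any(edges[, 1] == edges[, 2]))
    stop(sprintf("self-loop at area %d", edges[which(edges[, 1] == edges[, 2])[1], 1]))
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- edges[!duplicated(key), , drop = FALSE]
  nbs <- rep(list(integer(0)), J)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    nbs[[a]] <- c(nbs[[a]], b)
    nbs[[b]] <- c(nbs[[b]], a)
  }
  adjacency_graph(nbs, codes)
}

#' Read a district adjacency structure
#'
#' Supports three dialects:
#' \describe{
#'   \item{`winbugs_adj`}{the WinBUGS/GeoBUGS adjacency triplet: integer
#'     vectors `num` (neighbour counts), `adj` (concatenated neighbour lists)
#'     and `sumNumNeigh`. Symmetry of the listing is validated, not repaired.}
#'   \item{`edge_list`}{a two-column CSV of area codes, one undirected edge
#'     per row. Area index order is order of first appearance.}
#'   \item{`geojson_polygons`}{a GeoJSON FeatureCollection of (Multi)Polygons;
#'     adjacency is queen contiguity, i.e. two features sharing at least one
#'     boundary vertex after snapping coordinates at 1e-8 degrees.}
#' }
#'
#' @param source path to the file.
#' @param dialect one of `"winbugs_adj"`, `"edge_list"`, `"geojson_polygons"`.
#' @param id_property for GeoJSON input, the property naming each feature.
#' @param codes optional area codes for `winbugs_adj` input (the format itself
#'   carries none).
#' @return an [adjacency_graph].
#' @export
read_adjacency <- function(source,
                           dialect = c("winbugs_adj", "edge_list",
                                       "geojson_polygons"),
                           id_property = "id", codes = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(source)) stop("adjacency source not found: ", source)
  switch(dialect,
    winbugs_adj = .read_winbugs_adj(source, codes),
    edge_list = .read_edge_list(source),
    geojson_polygons = .read_geojson_adj(source, id_property))
}

.read_edge_list <- function(source) {
  df <- utils::read.csv(source, colClasses = "character",
                        strip.white = TRUE)
  if (ncol(df) < 2L) stop("edge list must have two columns of area codes")
  a <- df[[1]]; b <- df[[2]]
  codes <- unique(as.vector(t(cbind(a, b)))) # order of first appearance
  edges <- cbind(match(a, codes), match(b, codes))
  .graph_from_edges(edges, codes)
}

.extract_bugs_vector <- function(txt, name) {
  pat <- paste0(name, "\\s*=\\s*c\\(([^)]*)\\)")
  m <- regmatches(txt, regexpr(pat, txt, perl = TRUE))
  if (!length(m))
    stop("could not find vector '", name, "' in WinBUGS adjacency file")
  body <- sub(pat, "\\1", m, perl = TRUE)
  parts <- strsplit(body, "[,[:space:]]+")[[1]]
  as.integer(parts[nzchar(parts)])
}

.read_winbugs_adj <- function(source, codes = NULL) {
  txt <- paste(readLines(source, warn = FALSE), collapse = " ")
  num <- .extract_bugs_vector(txt, "num")
  adj <- .extract_bugs_vector(txt, "adj")
  if (sum(num) != length(adj))
    stop("WinBUGS adjacency: sum(num) does not match length(adj)")
  sm <- regexpr("sumNumNeigh\\s*=\\s*([0-9]+)", txt, perl = TRUE)
  if (sm != -1L) {
    snn <- as.integer(sub(".*sumNumNeigh\\s*=\\s*([0-9]+).*", "\\1",
                          regmatches(txt, sm)))
    if (snn != length(adj))
      stop("WinBUGS adjacency: sumNumNeigh does not match length(adj)")
  }
  ends <- cumsum(num)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  nbs <- lapply(seq_along(num), function(j)
    if (num[j] == 0L) integer(0) else adj[starts[j]:ends[j]])
  adjacency_graph(nbs, codes)
}

#' Write a graph in the WinBUGS adjacency dialect
#'
#' Round-trip companion to `read_adjacency(..., "winbugs_adj")`.
#'
#' @param graph an [adjacency_graph].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_winbugs_adj <- function(graph, path) {
  stopifnot(inherits(graph, "adjacency_graph"))
  adj <- unlist(graph$neighbours)
  txt <- sprintf("list(num = c(%s),\nadj = c(%s),\nsumNumNeigh = %d)\n",
                 paste(graph$n_neighbours, collapse = ", "),
                 paste(adj, collapse = ", "),
                 length(adj))
  writeLines(txt, path)
  invisible(path)
}

.polygon_vertices <- function(geom) {
  # returns a character vector of snapped "x|y" vertex keys for a geometry
  coords <- geom$coordinates
  type <- geom$type
  rings <- switch(type,
    Polygon = coords,
    MultiPolygon = do.call(c, coords),
    stop("unsupported geometry type: ", type))
  pts <- do.call(c, rings)
  xy <- vapply(pts, function(p)
    sprintf("%.8f|%.8f", round(as.numeric(p[[1]]), 8),
            round(as.numeric(p[[2]]), 8)), character(1))
  unique(xy)
}

.read_geojson_adj <- function(source, id_property) {
  gj <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("GeoJSON input is not a FeatureCollection")
  feats <- gj$features
  codes <- vapply(feats, function(f) {
    v <- f$properties[[id_property]]
    if (is.null(v)) stop("feature missing id property '", id_property, "'")
    as.character(v)
  }, character(1))
  verts <- lapply(feats, function(f) .polygon_vertices(f$geometry))
  J <- length(feats)
  # queen contiguity: any shared snapped vertex
  vert_df <- data.frame(key = unlist(verts),
                        area = rep(seq_len(J), lengths(verts)))
  edges <- NULL
  for (grp in split(vert_df$area, vert_df$key)) {
    u <- unique(grp)
    if (length(u) > 1L)
      edges <- rbind(edges, t(utils::combn(sort(u), 2L)))
  }
  if (is.null(edges)) {
    g <- adjacency_graph(rep(list(integer(0)), J), codes)
    return(g)
  }
  .graph_from_edges(edges, codes)
}

#' Rook-adjacency lattice graph
#'
#' Regular `rows` x `cols` grid, used as a synthetic geography in tests and
#' simulations. Areas are numbered row-major.
#'
#' @param rows,cols positive integers.
#' @return an [adjacency_graph] with `rows * cols` areas.
#' @export
lattice_graph <- function(rows, cols) {
  if (rows < 1L || cols < 1L) stop("lattice dimensions must be positive")
  J <- rows * cols
  idx <- function(r, c) (r - 1L) * cols + c
  nbs <- rep(list(integer(0)), J)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      j <- idx(r, c)
      nb <- integer(0)
      if (r > 1L) nb <- c(nb, idx(r - 1L, c))
      if (r < rows) nb <- c(nb, idx(r + 1L, c))
      if (c > 1L) nb <- c(nb, idx(r, c - 1L))
      if (c < cols) nb <- c(nb, idx(r, c + 1L))
      nbs[[j]] <- nb
    }
  }
  adjacency_graph(nbs)
}

#' Intrinsic CAR precision structure
#'
#' Builds the (improper) precision structure matrix `Q` of the intrinsic CAR
#' prior: `Q[j,j] = m_j` (neighbour count) and `Q[j,l] = -1` when `l` is a
#' neighbour of `j`. Every row sums to zero and `rank(Q) = J - c` where `c` is
#' the number of connected components (islands each count as a component).
#'
#' @param graph an [adjacency_graph].
#' @return object of class `icar_structure`: list with `Q`, `n_components`,
#'   `rank`, `components` (component id per area).
#' @export
icar_structure <- function(graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  J <- graph$n_areas
  Q <- matrix(0, J, J, dimnames = list(graph$codes, graph$codes))
  for (j in seq_len(J)) {
    Q[j, j] <- graph$n_neighbours[j]
    Q[j, graph$neighbours[[j]]] <- -1
  }
  comp <- .connected_components(graph)
  structure(
    list(Q = Q, n_components = max(comp), rank = J - max(comp),
         components = comp),
    class = "icar_structure")
}

.connected_components <- function(graph) {
  J <- graph$n_areas
  comp <- integer(J)
  cid <- 0L
  for (s in seq_len(J)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in graph$neighbours[[v]]) {
        if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
      }
    }
  }
  comp
}

#' @export
print.icar_structure <- function(x, ...) {
  cat(sprintf("icar_structure: %d areas, rank %d (%d component(s))\n",
              nrow(x$Q), x$rank, x$n_components))
  invisible(x)
}

#' Moran's I spatial autocorrelation
#'
#' Binary-weight Moran's I of a vector over an adjacency graph; used to check
#' that simulated structured effects are, and unstructured ones are not,
#' spatially autocorrelated.
#'
#' @param x numeric vector, one value per area.
#' @param graph an [adjacency_graph].
#' @return Moran's I statistic.
#' @export
morans_i <- function(x, graph) {
  stopifnot(inherits(graph, "adjacency_graph"),
            length(x) == graph$n_areas)
  xc <- x - mean(x)
  W <- sum(graph$n_neighbours)
  num <- 0
  for (j in seq_len(graph$n_areas)) {
    nb <- graph$neighbours[[j]]
    if (length(nb)) num <- num + xc[j] * sum(xc[nb])
  }
  (graph$n_areas / W) * num / sum(xc^2)
}
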