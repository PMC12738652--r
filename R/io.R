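#' Write barcode sets to a diagrams CSV
#'
#' One row per bar, columns `node_id`, `species`, `degree`, `birth_level`,
#' `death_level` (the string `"inf"` for essential bars).
#'
#' @param nodes list of [barcode_set()]s.
#' @param path output file.
#' @return (invisibly) the written data.frame.
#' @export
write_diagrams_csv <- function(nodes, path) {
  rows <- lapply(nodes, function(s) {
    do.call(rbind, lapply(c("B0u", "B1u", "B0v", "B1v"), function(ch) {
      d <- s[[ch]]
      if (nrow(d) == 0L) return(NULL)
      data.frame(node_id = s$node_id,
                 species = substr(ch, 3L, 3L),
                 degree = as.integer(substr(ch, 2L, 2L)),
                 birth_level = d$birth,
                 death_level = ifelse(is.infinite(d$death), "inf",
                                      as.character(d$death)))
    }))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(node_id = character(0), species = character(0),
                      degree = integer(0), birth_level = numeric(0),
                      death_level = character(0))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Read barcode sets from a diagrams CSV
#'
#' Inverse of [write_diagrams_csv()]. Channels with no bars come back empty.
#'
#' @param path CSV file.
#' @return list of [barcode_set()]s in node-id order.
#' @export
read_diagrams_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(tab$node_id)
  lapply(ids, function(id) {
    sub <- tab[tab$node_id == id, , drop = FALSE]
    get_diag <- function(sp, deg) {
      ss <- sub[sub$species == sp & sub$degree == deg, , drop = FALSE]
      persistence_diagram(ss$birth_level,
                          ifelse(ss$death_level == "inf", Inf,
                                 as.numeric(ss$death_level)),
                          degree = deg)
    }
    barcode_set(id,
                B0u = get_diag("u", 0L), B1u = get_diag("u", 1L),
                B0v = get_diag("v", 0L), B1v = get_diag("v", 1L))
  })
}

#' Write a field snapshot as CSV
#'
#' Columns `x`, `y`, `u`, `v` in vertex storage order.
#'
#' @param u,v [new_field()]s on the same grid.
#' @param path output file.
#' @return (invisibly) the written data.frame.
#' @export
write_field_csv <- function(u, v, path) {
  stopifnot(identical(u$grid, v$grid))
  tab <- cbind(grid_coords(u$grid), u = u$values, v = v$values)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Read a field snapshot CSV
#'
#' @param path CSV written by [write_field_csv()].
#' @return list with `u`, `v` ([new_field()]s) and the reconstructed `grid`.
#' @export
read_field_csv <- function(path) {
  tab <- utils::read.csv(path)
  xs <- sort(unique(tab$x)); ys <- sort(unique(tab$y))
  step <- if (length(xs) > 1L) xs[2] - xs[1] else
          if (length(ys) > 1L) ys[2] - ys[1] else 1
  grid <- build_grid(max(xs), max(ys), step)
  o <- order(tab$y, tab$x)
  list(u = new_field(grid, tab$u[o], "u"),
       v = new_field(grid, tab$v[o], "v"),
       grid = grid)
}

#' Write a distance matrix as CSV (node ids as header)
#'
#' @param dmat symmetric matrix from [distance_matrix()].
#' @param path output file.
#' @export
write_distance_csv <- function(dmat, path) {
  utils::write.csv(as.data.frame(dmat), path, row.names = TRUE)
}

#' Read a distance matrix CSV
#'
#' @param path CSV written by [write_distance_csv()].
#' @return symmetric numeric matrix with dimnames.
#' @export
read_distance_csv <- function(path) {
  tab <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  as.matrix(tab)
}
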