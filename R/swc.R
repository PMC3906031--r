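#' Write a morphology to an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`).  The soma is a
#' single node of type 1 at the soma center; each arbor contributes one
#' anchor node at its root's start point (child of the soma node) followed
#' by one node per segment endpoint.  Type codes follow the SWC
#' convention: 1 soma, 2 axon, 3 basal dendrite, 4 apical dendrite.
#' Coordinates are written with 4 decimals, so a round trip preserves them
#' to 1e-4 micrometres.
#'
#' @param m a `neuron_morphology`.
#' @param path output file path.
#' @param neurite_radius radius written for neurite nodes, micrometres.
#' @return `path`, invisibly.
#' @seealso [read_swc()]
#' @export
write_swc <- function(m, path, neurite_radius = 0.3) {
  seg <- m$segments
  type_code <- c(axon = 2L, basal = 3L, apical = 4L)[seg$kind]
  n <- nrow(seg)
  # node ids: 1 = soma; per arbor one anchor node; then one node per segment
  roots <- which(seg$parent == 0)
  anchor_id <- setNames(seq_along(roots) + 1L, seg$arbor[roots])
  seg_node <- seq_len(n) + 1L + length(roots)
  parent_node <- ifelse(seg$parent == 0,
                        anchor_id[as.character(seg$arbor)],
                        seg_node[pmax(seg$parent, 1L)])
  lines <- character(1L + length(roots) + n)
  lines[1] <- sprintf("1 1 %.4f %.4f %.4f %.4f -1", m$soma_center[1],
                      m$soma_center[2], m$soma_center[3], m$soma_radius)
  for (a in seq_along(roots)) {
    r <- roots[a]
    lines[1L + a] <- sprintf("%d %d %.4f %.4f %.4f %.4f 1", anchor_id[a],
                             type_code[r], seg$x0[r], seg$y0[r], seg$z0[r],
                             neurite_radius)
  }
  lines[1L + length(roots) + seq_len(n)] <-
    sprintf("%d %d %.4f %.4f %.4f %.4f %d", seg_node, type_code, seg$x1,
            seg$y1, seg$z1, neurite_radius, parent_node)
  writeLines(c("# SWC generated by mdfconn", lines), path)
  invisible(path)
}

#' Read a morphology from an SWC file
#'
#' Inverse of [write_swc()]: every node whose parent is a non-soma node
#' becomes a segment from the parent's coordinates to the node's; nodes
#' attached directly to the soma node are arbor anchor points.  Malformed
#' files (dangling parent ids, duplicate ids, cycles, missing soma) raise
#' a parse error naming the offending line.
#'
#' @param path SWC file path.
#' @return a `neuron_morphology`.
#' @export
read_swc <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  line_no <- which(keep)
  if (!length(line_no)) stop("SWC parse error: no data lines", call. = FALSE)
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop("SWC parse error at line ", line_no[bad[1]],
         ": expected 7 columns", call. = FALSE)
  tab <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(tab))
    stop("SWC parse error: non-numeric field at line ",
         line_no[which(apply(is.na(tab), 1, any))[1]], call. = FALSE)
  id <- as.integer(tab[, 1]); type <- as.integer(tab[, 2])
  parent <- as.integer(tab[, 7])
  if (anyDuplicated(id))
    stop("SWC parse error at line ", line_no[which(duplicated(id))[1]],
         ": duplicate node id", call. = FALSE)
  row_of <- setNames(seq_along(id), id)
  dangling <- which(parent != -1L & !(parent %in% id))
  if (length(dangling))
    stop("SWC parse error at line ", line_no[dangling[1]],
         ": parent id ", parent[dangling[1]], " not found", call. = FALSE)
  soma_rows <- which(type == 1L)
  if (length(soma_rows) != 1L)
    stop("SWC parse error: expected exactly one soma (type 1) node",
         call. = FALSE)
  soma <- soma_rows[1]
  # cycle / orphan check: every node must reach a root following parents
  depth <- rep(NA_integer_, length(id))
  for (i in seq_along(id)) {
    j <- i; hops <- 0L
    while (parent[j] != -1L) {
      j <- row_of[[as.character(parent[j])]]
      hops <- hops + 1L
      if (hops > length(id))
        stop("SWC parse error at line ", line_no[i],
             ": cycle in parent links", call. = FALSE)
    }
    depth[i] <- hops
  }
  neur <- which(type != 1L & parent != -1L &
                  type[row_of[as.character(parent)]] != 1L)
  kind_of <- function(tc) {
    k <- c(`2` = "axon", `3` = "basal", `4` = "apical")[as.character(tc)]
    ifelse(is.na(k), "basal", k)  # unknown dendrite-like codes -> basal
  }
  prow <- row_of[as.character(parent[neur])]
  seg <- data.frame(kind = kind_of(type[neur]), arbor = 0L, parent = 0L,
                    order = 0L,
                    x0 = tab[prow, 3], y0 = tab[prow, 4], z0 = tab[prow, 5],
                    x1 = tab[neur, 3], y1 = tab[neur, 4], z1 = tab[neur, 5],
                    stringsAsFactors = FALSE)
  # rebuild per-segment parent links, arbor ids and centrifugal orders
  seg_of_node <- setNames(seq_along(neur), id[neur])
  par_id <- parent[neur]
  seg$parent <- ifelse(par_id %in% id[neur],
                       seg_of_node[as.character(par_id)], 0L)
  n_children <- table(factor(seg$parent, levels = 0:nrow(seg)))
  ord <- integer(nrow(seg)); arb <- integer(nrow(seg))
  n_arb <- 0L
  idx <- order(depth[neur])  # parents before children
  for (i in idx) {
    p <- seg$parent[i]
    if (p == 0L) {
      n_arb <- n_arb + 1L
      arb[i] <- n_arb
      ord[i] <- 0L
    } else {
      arb[i] <- arb[p]
      ord[i] <- ord[p] + as.integer(n_children[[as.character(p)]] > 1L)
    }
  }
  seg$arbor <- arb
  seg$order <- ord
  morphology(seg, soma_center = tab[soma, 3:5], soma_radius = tab[soma, 6])
}
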