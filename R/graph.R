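# Skeleton -> graph conversion and twig pruning.  Branch pixels are skeleton
# pixels with >= 3 skeleton 8-neighbours; 8-adjacent branch pixels merge into
# one node cluster; the remaining (regular) pixels form chains traced between
# clusters.  Segment length is the sum of inter-pixel steps (1 orthogonal,
# sqrt(2) diagonal) including the step onto each terminal node cluster.

OFFS_UNIQUE <- list(
  list(d = c(0L, 1L), w = 1), list(d = c(1L, 0L), w = 1),
  list(d = c(1L, 1L), w = sqrt(2)), list(d = c(1L, -1L), w = sqrt(2))
)
OFFS_ALL <- list(
  list(d = c(0L, 1L), w = 1), list(d = c(0L, -1L), w = 1),
  list(d = c(1L, 0L), w = 1), list(d = c(-1L, 0L), w = 1),
  list(d = c(1L, 1L), w = sqrt(2)), list(d = c(1L, -1L), w = sqrt(2)),
  list(d = c(-1L, 1L), w = sqrt(2)), list(d = c(-1L, -1L), w = sqrt(2))
)

#' Convert a skeleton into a vessel graph
#'
#' Identifies branch nodes (clusters of 8-adjacent skeleton pixels having at
#' least three skeleton neighbours), endpoints (pixels with exactly one
#' neighbour), and the vessel segments running between them.  Each segment
#' carries its pixel count, step length (orthogonal steps count 1, diagonal
#' steps `sqrt(2)`, converted to micrometres via the spec) and, when a
#' diameter map is supplied, its mean diameter.
#'
#' @param skeleton An `octa_skeleton` or logical matrix.
#' @param diameters Optional [diameter_map()] result for per-segment mean
#'   diameters.
#' @param spec An [image_spec()].
#' @return An object of class `octa_graph` with tibbles `nodes` (branch
#'   clusters), `segments`, and `endpoints`, plus bookkeeping fields.
#' @export
build_vessel_graph <- function(skeleton, diameters = NULL, spec = image_spec()) {
  sk <- if (inherits(skeleton, "octa_skeleton")) skeleton$skeleton else skeleton != 0
  dims <- dim(sk)
  um_per_px <- spec$pixel_size_mm * 1000
  ski <- matrix(as.integer(sk), dims[1], dims[2])
  empty <- function() {
    structure(list(
      nodes = tibble(
        node = integer(), row = numeric(), col = numeric(),
        n_pixels = integer(), degree = integer(), comp = integer(),
        pixels = list()
      ),
      segments = tibble(
        segment = integer(), node_a = integer(), node_b = integer(),
        n_pixels = integer(), length_px = numeric(), length_um = numeric(),
        mean_diameter_um = numeric(), cycle = logical(), comp = integer(),
        pixels = list()
      ),
      endpoints = tibble(row = integer(), col = integer(), pixel = integer()),
      spec = spec, dims = dims, pruned = FALSE
    ), class = "octa_graph")
  }
  if (!any(sk)) return(empty())

  ncnt <- neighbour_count8(ski)
  branch <- ski == 1L & ncnt >= 3L
  regular <- ski == 1L & !branch
  comp_lab <- label_components(ski, 8L)
  clusters <- label_components(matrix(as.integer(branch), dims[1], dims[2]), 8L)
  chains <- label_components(matrix(as.integer(regular), dims[1], dims[2]), 8L)
  ncl <- max(clusters)
  nch <- max(chains)

  ep_idx <- which(ski == 1L & ncnt == 1L)
  endpoints <- tibble(
    row = (ep_idx - 1L) %% dims[1] + 1L,
    col = (ep_idx - 1L) %/% dims[1] + 1L,
    pixel = ep_idx
  )

  # nodes
  nodes <- empty()$nodes
  if (ncl > 0L) {
    cl_idx <- which(clusters > 0L)
    cl_lab <- clusters[cl_idx]
    npix <- tabulate(cl_lab, ncl)
    rsum <- as.numeric(rowsum((cl_idx - 1L) %% dims[1] + 1, cl_lab))
    csum <- as.numeric(rowsum((cl_idx - 1L) %/% dims[1] + 1, cl_lab))
    nodes <- tibble(
      node = seq_len(ncl),
      row = round(rsum / npix), col = round(csum / npix),
      n_pixels = npix, degree = 0L,
      comp = as.integer(comp_lab[cl_idx[match(seq_len(ncl), cl_lab)]]),
      pixels = unname(split(cl_idx, factor(cl_lab, levels = seq_len(ncl))))
    )
  }

  segments <- empty()$segments
  if (nch > 0L) {
    ch_idx <- which(chains > 0L)
    ch_lab <- chains[ch_idx]
    npix <- tabulate(ch_lab, nch)
    # internal step length and regular-regular degree
    internal <- numeric(nch)
    regm <- matrix(as.integer(regular), dims[1], dims[2])
    deg_reg <- matrix(0L, dims[1], dims[2])
    for (o in OFFS_ALL) {
      nb <- shift_mat(regm, o$d[1], o$d[2])
      deg_reg <- deg_reg + (regm == 1L & nb == 1L)
    }
    for (o in OFFS_UNIQUE) {
      nb <- shift_mat(regm, o$d[1], o$d[2])
      sel <- which(regm == 1L & nb == 1L)
      if (length(sel)) internal <- internal + o$w * tabulate(chains[sel], nch)
    }
    # attachments: regular pixel adjacent to a branch cluster
    att <- list()
    for (o in OFFS_ALL) {
      nbcl <- shift_mat(clusters, o$d[1], o$d[2])
      sel <- which(regm == 1L & nbcl > 0L)
      if (length(sel)) {
        att[[length(att) + 1L]] <- data.frame(
          chain = chains[sel], pixel = sel, cluster = nbcl[sel], w = o$w
        )
      }
    }
    att <- if (length(att)) do.call(rbind, att) else
      data.frame(chain = integer(), pixel = integer(), cluster = integer(), w = numeric())
    if (nrow(att)) {
      att <- att[order(att$chain, att$pixel, att$cluster, att$w), , drop = FALSE]
      att <- att[!duplicated(att[c("chain", "pixel", "cluster")]), , drop = FALSE]
      # prefer attachments at chain-terminal pixels, then lowest pixel index;
      # keep at most two per chain (its two ends)
      term <- deg_reg[att$pixel] <= 1L
      att <- att[order(att$chain, !term, att$pixel), , drop = FALSE]
      ord <- ave(seq_len(nrow(att)), att$chain, FUN = seq_along)
      att <- att[ord <= 2L, , drop = FALSE]
    }
    a_first <- att[!duplicated(att$chain), , drop = FALSE]
    a_second <- att[duplicated(att$chain), , drop = FALSE]
    node_a <- rep(NA_integer_, nch)
    node_b <- rep(NA_integer_, nch)
    end_a <- rep(NA_integer_, nch)
    end_b <- rep(NA_integer_, nch)
    attlen <- numeric(nch)
    node_a[a_first$chain] <- a_first$cluster
    end_a[a_first$chain] <- a_first$pixel
    node_b[a_second$chain] <- a_second$cluster
    end_b[a_second$chain] <- a_second$pixel
    attlen[a_first$chain] <- attlen[a_first$chain] + a_first$w
    attlen[a_second$chain] <- attlen[a_second$chain] + a_second$w
    # a chain with no attachments and no terminal pixel is a closed loop
    n_term <- tabulate(chains[which(regm == 1L & deg_reg <= 1L)], nch)
    cycle <- is.na(node_a) & n_term == 0L & npix > 2L
    length_px <- internal + attlen
    mean_diam <- rep(NA_real_, nch)
    if (!is.null(diameters)) {
      dsum <- rowsum(diameters$um[ch_idx], ch_lab)
      mean_diam[as.integer(rownames(dsum))] <- as.numeric(dsum) / npix[as.integer(rownames(dsum))]
    }
    segments <- tibble(
      segment = seq_len(nch), node_a = node_a, node_b = node_b,
      n_pixels = npix, length_px = length_px,
      length_um = length_px * um_per_px, mean_diameter_um = mean_diam,
      cycle = cycle,
      comp = as.integer(comp_lab[ch_idx[match(seq_len(nch), ch_lab)]]),
      pixels = unname(split(ch_idx, factor(ch_lab, levels = seq_len(nch))))
    )
  }
  if (nrow(nodes)) {
    ends <- c(segments$node_a, segments$node_b)
    dg <- tabulate(ends[!is.na(ends)], nrow(nodes))
    nodes$degree <- as.integer(dg)
  }
  structure(
    list(
      nodes = nodes, segments = segments, endpoints = endpoints,
      spec = spec, dims = dims, pruned = FALSE
    ),
    class = "octa_graph"
  )
}

#' @export
print.octa_graph <- function(x, ...) {
  cat(sprintf(
    "<octa_graph>%s %d branch nodes, %d segments, %d endpoints, total length %.2f mm\n",
    if (x$pruned) " (pruned)" else "", nrow(x$nodes), nrow(x$segments),
    nrow(x$endpoints), sum(x$segments$length_um) / 1000
  ))
  invisible(x)
}

#' Prune twigs and isolated structures from a vessel graph
#'
#' Removes, in a single pass: (i) endpoint-terminated segments whose step
#' length is below `twig_px` pixels, and (ii) connected components whose total
#' length is below `twig_px` (isolated specks).  Branch nodes left with two
#' incident segments are then dissolved by merging the two segments; nodes
#' left with one or zero are absorbed or dropped.  Set `iterate = TRUE` to
#' repeat the pass until no twig remains.
#'
#' @param graph An `octa_graph` from [build_vessel_graph()].
#' @param twig_px Twig length threshold in pixel steps, default 2.
#' @param iterate Repeat pruning to a fixpoint? Default `FALSE` (one pass).
#' @return A pruned `octa_graph`.
#' @export
prune_graph <- function(graph, twig_px = 2, iterate = FALSE) {
  stopifnot(inherits(graph, "octa_graph"))
  g <- graph
  repeat {
    before <- nrow(g$segments)
    g <- prune_pass(g, twig_px)
    if (!iterate || nrow(g$segments) == before) break
  }
  g$pruned <- TRUE
  g
}

prune_pass <- function(graph, twig_px) {
  seg <- graph$segments
  nod <- graph$nodes
  if (nrow(seg)) {
    dangling <- (is.na(seg$node_a) | is.na(seg$node_b)) & !seg$cycle
    seg <- seg[!(dangling & seg$length_px < twig_px), , drop = FALSE]
    # isolated structures: whole components below the threshold
    if (nrow(seg)) {
      comp_len <- rowsum(seg$length_px, seg$comp)
      bad <- as.integer(rownames(comp_len))[comp_len[, 1] < twig_px]
      seg <- seg[!(seg$comp %in% bad), , drop = FALSE]
    }
  }
  nod <- nod[nod$comp %in% unique(seg$comp), , drop = FALSE]

  # mutable vectors for dissolution
  alive <- rep(TRUE, nrow(seg))
  na_ <- seg$node_a
  nb_ <- seg$node_b
  len <- seg$length_px
  npx <- seg$n_pixels
  dia <- seg$mean_diameter_um
  cyc <- seg$cycle
  pxl <- seg$pixels
  node_ends <- function(id) {
    rows <- which(alive & (na_ == id | nb_ == id))
    slots <- lapply(rows, function(r) {
      s <- c(if (isTRUE(na_[r] == id)) "a", if (isTRUE(nb_[r] == id)) "b")
      cbind(rep(r, length(s)), s)
    })
    if (length(slots)) do.call(rbind, slots) else cbind(integer(), character())
  }
  drop_node <- rep(FALSE, nrow(nod))
  if (nrow(nod)) {
    for (i in seq_len(nrow(nod))) {
      id <- nod$node[i]
      en <- node_ends(id)
      dg <- nrow(en)
      if (dg >= 3L) next
      cn <- nod$n_pixels[i]
      extra <- max(cn - 1L, 0L)   # intra-cluster steps when absorbing pixels
      if (dg == 0L) {
        drop_node[i] <- TRUE
      } else if (dg == 1L) {
        r <- as.integer(en[1, 1])
        if (en[1, 2] == "a") na_[r] <- NA_integer_ else nb_[r] <- NA_integer_
        npx[r] <- npx[r] + cn
        len[r] <- len[r] + extra
        pxl[[r]] <- c(pxl[[r]], nod$pixels[[i]])
        drop_node[i] <- TRUE
      } else if (dg == 2L) {
        r1 <- as.integer(en[1, 1])
        r2 <- as.integer(en[2, 1])
        if (r1 == r2) {
          # both ends of one segment: becomes a free cycle
          na_[r1] <- NA_integer_
          nb_[r1] <- NA_integer_
          cyc[r1] <- TRUE
        } else {
          other2 <- if (en[2, 2] == "a") nb_[r2] else na_[r2]
          if (en[1, 2] == "a") na_[r1] <- other2 else nb_[r1] <- other2
          w <- c(npx[r1], npx[r2])
          dia[r1] <- if (all(is.na(dia[c(r1, r2)]))) NA_real_ else
            sum(dia[c(r1, r2)] * w, na.rm = TRUE) / sum(w[!is.na(dia[c(r1, r2)])])
          len[r1] <- len[r1] + len[r2] + extra
          pxl[[r1]] <- c(pxl[[r1]], pxl[[r2]], nod$pixels[[i]])
          alive[r2] <- FALSE
          # rewire the far node's reference from r2 to r1 (ids unchanged)
        }
        npx[r1] <- npx[r1] + if (r1 == r2) cn else npx[r2] + cn
        drop_node[i] <- TRUE
      }
    }
  }
  seg <- seg[alive, , drop = FALSE]
  keep <- which(alive)
  seg$node_a <- na_[keep]
  seg$node_b <- nb_[keep]
  seg$length_px <- len[keep]
  seg$n_pixels <- npx[keep]
  seg$mean_diameter_um <- dia[keep]
  seg$cycle <- cyc[keep]
  seg$pixels <- pxl[keep]
  seg$length_um <- seg$length_px * graph$spec$pixel_size_mm * 1000
  nod <- nod[!drop_node, , drop = FALSE]
  if (nrow(nod)) {
    ends <- c(seg$node_a, seg$node_b)
    ends <- ends[!is.na(ends)]
    nod$degree <- as.integer(vapply(nod$node, function(id) sum(ends == id), 1L))
  }
  out <- graph
  out$segments <- seg
  out$nodes <- nod
  # endpoints: recompute from surviving segment free ends is not possible
  # without re-tracing; retain only endpoints on surviving pixels
  if (nrow(out$endpoints)) {
    live_px <- unlist(seg$pixels, use.names = FALSE)
    out$endpoints <- out$endpoints[out$endpoints$pixel %in% live_px, , drop = FALSE]
  }
  out
}
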