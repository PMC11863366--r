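#' Identify molecular aggregates under periodic boundary conditions
#'
#' Single-linkage clustering of the selected residues: two residues belong
#' to one cluster when a chain of selected-atom pairs, each within
#' `cutoff` under the minimum-image convention, links them. Distances are
#' computed with a periodic cell list; membership is evaluated at a single
#' chosen frame (aggregation is treated as fixed over the analysis range,
#' matching the cluster-then-analyze workflow).
#'
#' @param system an `md_system`.
#' @param selection atoms to cluster (string, ids or `atom_selection`);
#'   typically the aggregate's heavy atoms.
#' @param cutoff linkage distance in Angstrom (3.5 is a common heavy-atom
#'   contact criterion in the micelle literature).
#' @param frame 0-based frame index at which clusters are identified.
#' @return a `cluster_set`: list of clusters (integer residue-id vectors),
#'   ordered by decreasing size with ties broken by smallest residue id,
#'   plus the cutoff and frame used.
#' @examples
#' sys <- make_fixture("sphere", radius = 8, spacing = 3, box = c(60, 60, 60))
#' find_clusters(sys, "all", cutoff = 3.5)
#' @export
find_clusters <- function(system, selection, cutoff = 3.5, frame = 0L) {
  stopifnot(cutoff > 0)
  idx <- resolve_selection(system, selection, "selection")
  if (!length(idx))
    return(structure(list(clusters = list(), cutoff = cutoff,
                          frame = as.integer(frame)),
                     class = "cluster_set"))
  fr <- iter_frames(system, frame, frame + 1L)[[1]]
  xyz <- fr$xyz[idx, , drop = FALSE]
  lab <- cpp_cluster_labels(xyz, fr$box, cutoff)
  resid <- system$atoms$resid[match(idx, system$atoms$id)]
  # residues bridge atom-level components: merge labels sharing a residue
  merged <- merge_labels_by_group(lab, resid)
  split_res <- split(resid, merged)
  clusters <- lapply(unname(split_res), function(r) sort(unique(r)))
  ord <- order(-lengths(clusters),
               vapply(clusters, min, 0L))
  structure(list(clusters = clusters[ord], cutoff = cutoff,
                 frame = as.integer(frame)),
            class = "cluster_set")
}

# union labels that co-occur within a group (residue)
merge_labels_by_group <- function(lab, group) {
  parent <- seq_len(max(lab))
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (ls in split(lab, group)) {
    u <- unique(ls)
    if (length(u) > 1L) {
      for (k in 2:length(u)) {
        a <- find(u[1])
        b <- find(u[k])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  vapply(lab, find, 0L)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s), cutoff %.2f A, frame %d\n",
              length(x$clusters), x$cutoff, x$frame))
  for (i in seq_along(x$clusters)) {
    r <- x$clusters[[i]]
    shown <- paste(head(r, 12), collapse = " ")
    if (length(r) > 12) shown <- paste(shown, "...")
    cat(sprintf("  %d: %d: %s\n", i, length(r), shown))
  }
  invisible(x)
}

#' @export
length.cluster_set <- function(x) length(x$clusters)

#' Reassemble molecules split across periodic boundaries
#'
#' Makes each residue contiguous (every atom translated by integer box
#' vectors to the minimum image of the residue's first atom) and then
#' stitches the residues of the given set together: residues are placed by
#' breadth-first traversal of their contact graph, each minimum-imaged to
#' its already-placed neighbor, starting from the seed (first) residue.
#' This reproduces the unwrapped geometry even for aggregates wider than
#' half a box length, where a single global minimum image is ambiguous.
#'
#' @param system an `md_system`.
#' @param residues integer residue ids to treat as one aggregate (default:
#'   all residues).
#' @param cutoff contact distance (Angstrom) used to stitch residues.
#' @param frames 0-based frame indices to process (default: all).
#' @return the system with modified coordinates.
#' @export
make_whole <- function(system, residues = NULL, cutoff = 3.5,
                       frames = NULL) {
  residues <- residues %||% sort(unique(system$atoms$resid))
  fi <- (frames %||% (seq_along(system$frames) - 1L)) + 1L
  for (k in fi) {
    system$frames[[k]] <- make_whole_frame(system$frames[[k]],
                                           system$atoms, residues, cutoff)
  }
  system
}

make_whole_frame <- function(fr, atoms, residues, cutoff) {
  L <- fr$box
  xyz <- fr$xyz
  in_set <- atoms$resid %in% residues
  ridx <- split(which(in_set), atoms$resid[in_set])
  # 1. make each residue contiguous around its first atom
  for (rn in names(ridx)) {
    ai <- ridx[[rn]]
    if (length(ai) < 2L) next
    ref <- xyz[ai[1], ]
    d <- xyz[ai, , drop = FALSE] - rep(ref, each = length(ai))
    shift <- round(d / rep(L, each = length(ai)))
    xyz[ai, ] <- xyz[ai, , drop = FALSE] - shift * rep(L, each = length(ai))
    ext <- apply(xyz[ai, , drop = FALSE], 2, function(v) diff(range(v)))
    if (any(ext > L / 2))
      warn_fmt("residue %s spans more than half the box after unwrapping;
  its minimum image is ambiguous", rn)
  }
  # 2. stitch residues: BFS over the minimum-image contact graph, each
  # residue placed relative to its already-placed neighbour (always closer
  # than half a box), so aggregates wider than L/2 reassemble correctly
  nres <- length(ridx)
  if (nres > 1L) {
    centers <- t(vapply(ridx, function(ai)
      colMeans(xyz[ai, , drop = FALSE]), numeric(3)))
    # conservative contact bound: centers within cutoff + both radii
    radii <- vapply(seq_len(nres), function(i) {
      ai <- ridx[[i]]
      ctr <- centers[i, ]
      sqrt(max(rowSums((xyz[ai, , drop = FALSE] -
                          rep(ctr, each = length(ai)))^2)))
    }, 0)
    placed <- rep(FALSE, nres)
    placed[1] <- TRUE
    queue <- 1L
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      d <- centers - rep(centers[cur, ], each = nres)
      dm <- d - round(d / rep(L, each = nres)) * rep(L, each = nres)
      md <- sqrt(rowSums(dm^2))
      nb <- which(!placed & md <= cutoff + radii + radii[cur] + 1e-9)
      for (j in nb) {
        shift <- round((centers[j, ] - centers[cur, ] - dm[j, ]) / L)
        if (any(shift != 0)) {
          ai <- ridx[[j]]
          xyz[ai, ] <- xyz[ai, , drop = FALSE] -
            rep(shift * L, each = length(ai))
          centers[j, ] <- centers[j, ] - shift * L
        }
        placed[j] <- TRUE
        queue <- c(queue, j)
      }
      if (!length(queue) && !all(placed)) {
        # disconnected at this cutoff: fall back to seed minimum image
        j <- which(!placed)[1]
        shift <- round((centers[j, ] - centers[1, ]) / L)
        ai <- ridx[[j]]
        xyz[ai, ] <- xyz[ai, , drop = FALSE] -
          rep(shift * L, each = length(ai))
        centers[j, ] <- centers[j, ] - shift * L
        placed[j] <- TRUE
        queue <- j
      }
    }
  }
  fr$xyz <- xyz
  fr
}

#' Center an aggregate in the simulation box
#'
#' For every frame the chosen cluster is made whole ([make_whole()]) and
#' the whole system translated so that the cluster's center of geometry
#' sits at the box center; all other atoms are wrapped back into the
#' primary box while the cluster itself is kept contiguous. Centering a
#' wrapped trajectory this way removes periodic-boundary artifacts from
#' subsequent interface and density analyses.
#'
#' @param system an `md_system`.
#' @param cluster integer residue ids of the aggregate (e.g. one entry of
#'   [find_clusters()]'s result).
#' @param in_memory return the modified system (`TRUE`) or write it to
#'   `out_path` (`FALSE`).
#' @param out_path output trajectory path (only with `in_memory = FALSE`).
#' @param cutoff stitching cutoff passed to [make_whole()].
#' @return the modified `md_system` (invisibly the path when writing).
#' @export
center_cluster <- function(system, cluster, in_memory = TRUE,
                           out_path = NULL, cutoff = 3.5) {
  if (!length(cluster)) stop_fmt("cluster must contain at least one residue")
  if (in_memory && !is.null(out_path))
    stop_fmt("out_path cannot be combined with in_memory = TRUE")
  if (!in_memory && is.null(out_path))
    stop_fmt("out_path is required with in_memory = FALSE")
  cl_atoms <- which(system$atoms$resid %in% cluster)
  if (!length(cl_atoms)) stop_fmt("no atoms belong to the given residues")
  system <- make_whole(system, residues = cluster, cutoff = cutoff)
  for (k in seq_along(system$frames)) {
    fr <- system$frames[[k]]
    L <- fr$box
    cog <- colMeans(fr$xyz[cl_atoms, , drop = FALSE])
    fr$xyz <- fr$xyz + rep(L / 2 - cog, each = nrow(fr$xyz))
    others <- setdiff(seq_len(nrow(fr$xyz)), cl_atoms)
    if (length(others)) {
      x <- fr$xyz[others, , drop = FALSE]
      fr$xyz[others, ] <- x - floor(x / rep(L, each = length(others))) *
        rep(L, each = length(others))
    }
    system$frames[[k]] <- fr
  }
  if (in_memory) return(system)
  write_trajectory(system, out_path)
  invisible(out_path)
}
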