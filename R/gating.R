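# The comparator arm: CLR normalization of ADT counts, sequential
# surface-marker gating, and gate-threshold optimization by minimizing the
# normalized Shannon-Wiener index of the gated subsets.

#' Centered log-ratio normalization of ADT counts
#'
#' For a vector `x` (one cell's marker panel under `per_cell`, or one
#' marker's cells under `per_marker`), the normalized value is
#' \eqn{clr_i = \ln(1 + x_i / g)} with the geometric mean
#' \eqn{g = \exp(\sum_{x_j > 0} \ln x_j / L)}, where `L` is the full vector
#' length including zeros. Zero entries map to zero; an all-zero vector stays
#' all-zero. With `batchwise = TRUE` the `per_marker` margin is computed
#' within each batch separately (antibody staining intensity is
#' batch-specific).
#'
#' @param adt an [adt_matrix()].
#' @param margin `"per_cell"` (across the panel, default) or `"per_marker"`
#'   (across cells).
#' @param batchwise normalize within batches (only meaningful for
#'   `per_marker`; `per_cell` vectors never span batches).
#' @return A `normalized_adt`: list with `values` (cells x markers), `cells`,
#'   `markers`, `batch`, and normalization metadata.
#' @export
clr_normalize <- function(adt, margin = c("per_cell", "per_marker"),
                          batchwise = FALSE) {
  margin <- match.arg(margin)
  counts <- adt$counts
  clr_vec <- function(x) {
    pos <- x > 0
    if (!any(pos)) return(x * 0)
    g <- exp(sum(log(x[pos])) / length(x))
    log1p(x / g)
  }
  if (margin == "per_cell") {
    values <- t(apply(counts, 1L, clr_vec))
    dimnames(values) <- dimnames(counts)
  } else {
    values <- counts * 0
    groups <- if (batchwise) split(seq_len(nrow(counts)), adt$batch)
              else list(seq_len(nrow(counts)))
    for (rows in groups) {
      values[rows, ] <- apply(counts[rows, , drop = FALSE], 2L, clr_vec)
    }
  }
  n_zero <- sum(rowSums(counts) == 0)
  if (margin == "per_cell" && n_zero > 0) {
    warning(n_zero, " cell(s) with an all-zero ADT panel left at zero")
  }
  structure(list(values = values, cells = adt$cells, markers = adt$markers,
                 batch = adt$batch,
                 method = "clr", margin = margin, batchwise = batchwise),
            class = "normalized_adt")
}

#' Gate specifications
#'
#' A gate spec is an ordered list of nodes. Each node carries a subset label,
#' a set of marker constraints (`above` means strictly greater than the
#' threshold, `below` strictly less, on the normalized scale), and a consume
#' flag: cells assigned at a consuming node are removed from all downstream
#' nodes, mirroring sequential sorting-like gating.
#'
#' @param label subset label assigned by the node.
#' @param markers data.frame with columns `marker`, `direction`
#'   (`"above"`/`"below"`), `threshold`.
#' @param consume remove assigned cells from later nodes (default `TRUE`).
#' @return A `gate_node` / `gate_spec` object.
#' @export
gate_node <- function(label, markers, consume = TRUE) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  stopifnot(all(c("marker", "direction", "threshold") %in% names(markers)),
            all(markers$direction %in% c("above", "below")),
            all(is.finite(markers$threshold)))
  structure(list(label = as.character(label), markers = markers,
                 consume = isTRUE(consume)), class = "gate_node")
}

#' @rdname gate_node
#' @param ... `gate_node` objects, in gating order.
#' @export
gate_spec <- function(...) {
  nodes <- list(...)
  if (length(nodes) == 1L && is.list(nodes[[1L]]) &&
      !inherits(nodes[[1L]], "gate_node")) {
    nodes <- nodes[[1L]]
  }
  stopifnot(all(vapply(nodes, inherits, logical(1L), "gate_node")))
  structure(nodes, class = "gate_spec")
}

#' Default Th gating hierarchy
#'
#' Reconstructs the classic sequential sort-gate hierarchy on the eight
#' surface markers: Treg (CD25 high, CD127 low) is consumed first, then Tfh
#' (CXCR5+ CCR10-), Th22 (CCR10+ CXCR5-), and the chemokine-receptor splits
#' Th1 (CCR6- CXCR3+ CCR4-), Th1-17 (CCR6+ CXCR3+ CCR4-), Th17 (CCR6+ CXCR3-
#' CCR4+), Th2a (CCR6- CXCR3- CCR4+ CRTh2+) and Th2 (same but CRTh2-). An
#' optional leading effector/memory node (NOT CCR7+CD45RA+) can be enabled
#' when those markers are in the panel; it is off by default because typical
#' input cells are already memory-sorted.
#'
#' @param thresholds named numeric vector/list of per-marker thresholds on
#'   the normalized scale. Must cover CD25, CD127, CXCR5, CXCR3, CCR6, CCR4,
#'   CRTh2, CCR10 (plus CCR7, CD45RA when `memory_pregate`).
#' @param memory_pregate prepend a consuming node that labels CCR7+CD45RA+
#'   cells `"naive"`.
#' @return A [gate_spec()].
#' @export
default_gate_spec <- function(thresholds, memory_pregate = FALSE) {
  th <- function(m) {
    v <- thresholds[[m]]
    if (is.null(v) || is.na(v)) stop("no threshold for marker ", m)
    v
  }
  con <- function(...) {
    x <- list(...)
    data.frame(marker = vapply(x, `[[`, character(1L), 1L),
               direction = vapply(x, `[[`, character(1L), 2L),
               threshold = vapply(x, function(e) th(e[[1L]]), numeric(1L)),
               stringsAsFactors = FALSE)
  }
  nodes <- list()
  if (memory_pregate) {
    nodes <- c(nodes, list(gate_node("naive", con(list("CCR7", "above"),
                                                  list("CD45RA", "above")))))
  }
  nodes <- c(nodes, list(
    gate_node("Treg", con(list("CD25", "above"), list("CD127", "below"))),
    gate_node("Tfh", con(list("CXCR5", "above"), list("CCR10", "below"))),
    gate_node("Th22", con(list("CCR10", "above"), list("CXCR5", "below"))),
    gate_node("Th1", con(list("CCR6", "below"), list("CXCR3", "above"),
                         list("CCR4", "below"))),
    gate_node("Th1-17", con(list("CCR6", "above"), list("CXCR3", "above"),
                            list("CCR4", "below"))),
    gate_node("Th17", con(list("CCR6", "above"), list("CXCR3", "below"),
                          list("CCR4", "above"))),
    gate_node("Th2a", con(list("CCR6", "below"), list("CXCR3", "below"),
                          list("CCR4", "above"), list("CRTh2", "above"))),
    gate_node("Th2", con(list("CCR6", "below"), list("CXCR3", "below"),
                         list("CCR4", "above"), list("CRTh2", "below")))))
  gate_spec(nodes)
}

#' Apply a sequential gate hierarchy
#'
#' Cells are tested against the nodes in order; the first satisfied consuming
#' node assigns its label and removes the cell from later nodes. Cells
#' satisfying no node are labeled `"ungated"`. Markers absent from the ADT
#' panel may be supplied through `rna_fallback` (e.g. CCR10 assessed from RNA
#' when not in the antibody panel); a marker available in neither is a
#' configuration error.
#'
#' @param norm a [clr_normalize()] result.
#' @param spec a [gate_spec()].
#' @param rna_fallback optional cells x markers matrix of per-cell expression
#'   values for markers missing from the panel (rows aligned with
#'   `norm$values`).
#' @return Character vector of per-cell subset labels, named by cell.
#' @export
apply_gate_sequence <- function(norm, spec, rna_fallback = NULL) {
  values <- norm$values
  marker_values <- function(m) {
    if (m %in% colnames(values)) return(values[, m])
    if (!is.null(rna_fallback) && m %in% colnames(rna_fallback)) {
      return(rna_fallback[, m])
    }
    stop("configuration error: marker ", m,
         " not in the ADT panel and no fallback given", call. = FALSE)
  }
  needed <- unique(unlist(lapply(spec, function(nd) nd$markers$marker)))
  for (m in needed) marker_values(m)  # validate upfront

  n <- nrow(values)
  labels <- rep("ungated", n)
  free <- rep(TRUE, n)
  for (node in spec) {
    cond <- free
    for (k in seq_len(nrow(node$markers))) {
      v <- marker_values(node$markers$marker[k])
      thr <- node$markers$threshold[k]
      cond <- cond & if (node$markers$direction[k] == "above") v > thr else v < thr
    }
    labels[cond & labels == "ungated"] <- node$label
    if (node$consume) free[cond] <- FALSE
  }
  stats::setNames(labels, rownames(values))
}

#' Optimize gate thresholds by minimizing the Shannon index
#'
#' Searches threshold combinations (exhaustively over the Cartesian product
#' of the per-marker candidate grids, or by coordinate descent for large
#' grids) for the specification whose gated subsets are most focused on
#' transcriptome clusters: the objective is the mean of the defined
#' per-subset normalized Shannon indices (subsets under the `min_cells` rule
#' are excluded). Deterministic: ties keep the first minimum in grid order
#' (`expand.grid` row order; for coordinate descent, sweep order). Note that
#' coordinate descent may stop in a local minimum.
#'
#' @param norm a [clr_normalize()] result.
#' @param grids named list of candidate threshold vectors per marker.
#' @param clusters per-cell cluster labels aligned with `norm$values` rows.
#' @param spec_builder function(thresholds) -> [gate_spec()]; default
#'   [default_gate_spec()].
#' @param rna_fallback see [apply_gate_sequence()].
#' @param min_cells see [shannon_accuracy()].
#' @param method `"exhaustive"` (default) or `"coordinate"`.
#' @return list: `spec` (the arg-min gate spec), `thresholds`, `objective`
#'   (achieved mean Shannon), `labels` (per-cell labels under the best spec)
#'   and, for exhaustive search, `report` (every combination with its
#'   objective).
#' @export
optimize_gate_thresholds <- function(norm, grids, clusters,
                                     spec_builder = default_gate_spec,
                                     rna_fallback = NULL, min_cells = 8L,
                                     method = c("exhaustive", "coordinate")) {
  method <- match.arg(method)
  stopifnot(length(clusters) == nrow(norm$values))
  evaluate <- function(thresholds) {
    spec <- spec_builder(thresholds)
    labels <- apply_gate_sequence(norm, spec, rna_fallback = rna_fallback)
    s <- shannon_by_subset(labels, clusters, min_cells = min_cells)
    obj <- if (any(s$defined)) mean(s$shannon[s$defined]) else NA_real_
    list(objective = obj, labels = labels, spec = spec)
  }
  if (method == "exhaustive") {
    combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
    objectives <- numeric(nrow(combos))
    best <- NULL
    best_row <- NA_integer_
    for (k in seq_len(nrow(combos))) {
      res <- evaluate(as.list(combos[k, , drop = FALSE]))
      objectives[k] <- res$objective
      if (!is.na(res$objective) &&
          (is.null(best) || res$objective < best$objective)) {
        best <- res
        best_row <- k
      }
    }
    if (is.null(best)) {
      stop("optimization error: no threshold combination gated >= ",
           min_cells, " cells into any subset", call. = FALSE)
    }
    report <- cbind(combos, objective = objectives)
    return(list(spec = best$spec,
                thresholds = as.list(combos[best_row, , drop = FALSE]),
                objective = best$objective, labels = best$labels,
                report = report))
  }
  # coordinate descent from each grid's first candidate
  current <- lapply(grids, `[[`, 1L)
  best <- evaluate(current)
  repeat {
    improved <- FALSE
    for (m in names(grids)) {
      for (cand in grids[[m]]) {
        trial <- current
        trial[[m]] <- cand
        res <- evaluate(trial)
        if (!is.na(res$objective) &&
            (is.na(best$objective) || res$objective < best$objective)) {
          best <- res
          current <- trial
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  if (is.na(best$objective)) {
    stop("optimization error: no threshold combination gated >= ",
         min_cells, " cells into any subset", call. = FALSE)
  }
  list(spec = best$spec, thresholds = current, objective = best$objective,
       labels = best$labels, report = NULL)
}

#' Read / write a gate spec config file
#'
#' Human-editable YAML: a `nodes` list, each with `label`, optional
#' `consume`, and a `markers` list of `{marker, direction, threshold}`
#' entries.
#'
#' @param path file path.
#' @return [read_gate_spec()]: a [gate_spec()]. [write_gate_spec()]: `path`,
#'   invisibly.
#' @export
read_gate_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$nodes)) .stop_format("gate spec file has no 'nodes' entry")
  nodes <- lapply(cfg$nodes, function(nd) {
    mk <- do.call(rbind, lapply(nd$markers, function(m) {
      data.frame(marker = m$marker, direction = m$direction,
                 threshold = as.numeric(m$threshold),
                 stringsAsFactors = FALSE)
    }))
    gate_node(nd$label, mk, consume = if (is.null(nd$consume)) TRUE else nd$consume)
  })
  gate_spec(nodes)
}

#' @rdname read_gate_spec
#' @param spec a [gate_spec()].
#' @export
write_gate_spec <- function(spec, path) {
  nodes <- lapply(spec, function(nd) {
    list(label = nd$label, consume = nd$consume,
         markers = lapply(seq_len(nrow(nd$markers)), function(k) {
           list(marker = nd$markers$marker[k],
                direction = nd$markers$direction[k],
                threshold = nd$markers$threshold[k])
         }))
  })
  yaml::write_yaml(list(nodes = nodes), path)
  invisible(path)
}
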