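## Evolutionary rates through time: 1-Myr time slicing of per-branch rates
## with per-slice medians and a Loess trend, overall and per group.

#' Collate branch rates crossing each time slice
#'
#' Slices the tree at regular intervals between `from_ma` and `to_ma`.  A
#' branch with parent age p and child age c crosses slice t iff
#' `c <= t < p` (half-open, so a branch ending exactly at a slice is not
#' double-counted with its child).  Each crossed slice receives the
#' branch's rate once.
#'
#' @param tree a [time_tree()] with `branch_rate` annotations.
#' @param from_ma oldest slice (Ma); must exceed `to_ma`.
#' @param to_ma youngest slice (Ma).
#' @param step slice spacing in Myr (default 1).
#' @param scope optional character vector of tip labels; only branches all
#'   of whose descendant tips are in `scope` contribute (use to exclude
#'   outgroup branches).
#' @param group label attached to the series (default "all").
#' @return a data.frame of class `rate_series` with columns `slice_ma`,
#'   `n_branches`, `median`; the per-slice rate multisets are in
#'   `attr(, "rates")` and the group label in `attr(, "group")`.
#' @export
slice_rates <- function(tree, from_ma, to_ma, step = 1, scope = NULL,
                        group = "all") {
  stopifnot(inherits(tree, "time_tree"))
  if (is.null(tree$branch_rate) || all(is.na(tree$branch_rate)))
    stop("tree has no branch rates")
  if (!(from_ma > to_ma)) stop("from_ma must be greater than to_ma")
  phy <- tree$phylo
  edge <- phy$edge
  p_age <- tree$node_age[edge[, 1]]
  c_age <- tree$node_age[edge[, 2]]
  rates <- tree$branch_rate
  keep <- !is.na(rates)
  if (!is.null(scope)) {
    tips <- clade_node_tips_all(phy)
    keep <- keep & vapply(edge[, 2], function(nd)
      all(tips[[nd]] %in% scope), logical(1))
  }
  slice_ma <- seq(from_ma, to_ma, by = -abs(step))
  rate_sets <- lapply(slice_ma, function(t) {
    rates[keep & c_age <= t & t < p_age]
  })
  out <- data.frame(slice_ma = slice_ma,
                    n_branches = lengths(rate_sets),
                    median = vapply(rate_sets, function(r)
                      if (length(r)) stats::median(r) else NA_real_, numeric(1)))
  attr(out, "rates") <- rate_sets
  attr(out, "group") <- group
  class(out) <- c("rate_series", "data.frame")
  out
}

## tip labels below every node (tips included), indexed by node number
clade_node_tips_all <- function(phylo) {
  ntip <- ape::Ntip(phylo)
  sets <- vector("list", ntip + phylo$Nnode)
  for (t in seq_len(ntip)) sets[[t]] <- phylo$tip.label[t]
  edge <- reorder(phylo, "postorder")$edge
  for (e in seq_len(nrow(edge)))
    sets[[edge[e, 1]]] <- c(sets[[edge[e, 1]]], sets[[edge[e, 2]]])
  sets
}

#' Loess trend through per-slice median rates
#'
#' Fits a locally weighted polynomial regression of the slice medians on
#' slice time and returns fitted values on the slice grid.
#'
#' @param series a [slice_rates()] result.
#' @param span Loess smoothing parameter (default 0.75).
#' @param degree local polynomial degree (default 2).
#' @return a data.frame of class `loess_trend` with `slice_ma`, `median`,
#'   `fitted` (defined wherever the median is defined).
#' @export
loess_trend <- function(series, span = 0.75, degree = 2) {
  stopifnot(inherits(series, "rate_series"))
  ok <- !is.na(series$median)
  if (sum(ok) < 5L) stop("need at least 5 defined slice medians for a trend")
  fit <- stats::loess(median ~ slice_ma, data = series[ok, ],
                      span = span, degree = degree,
                      control = stats::loess.control(surface = "direct"))
  out <- data.frame(slice_ma = series$slice_ma,
                    median = series$median,
                    fitted = NA_real_)
  out$fitted[ok] <- stats::predict(fit, newdata = series$slice_ma[ok])
  attr(out, "span") <- span
  attr(out, "group") <- attr(series, "group")
  class(out) <- c("loess_trend", "data.frame")
  out
}

#' Per-group rate-through-time series
#'
#' Branches are assigned to groups by the clade membership of their
#' descendant tips: a branch belongs to a group iff all its descendant
#' tips do (so each group's stem branch is included).  Branches whose
#' descendants span several groups, or include unassigned tips, are
#' excluded.  A tip claimed by two groups is an error.
#'
#' @param tree a [time_tree()] with branch rates.
#' @param metadata a [taxon_metadata()] supplying clade labels, or a named
#'   list clade -> tip labels via `groups`.
#' @param from_ma,to_ma,step slicing window, as [slice_rates()].
#' @param groups optional named list clade -> tip labels (overrides
#'   `metadata`).
#' @return named list of `rate_series`, one per group; groups absent from
#'   the tree give an empty series with a warning.
#' @export
rates_by_group <- function(tree, metadata = NULL, from_ma, to_ma, step = 1,
                           groups = NULL) {
  stopifnot(inherits(tree, "time_tree"))
  if (is.null(groups)) {
    if (is.null(metadata)) stop("supply either metadata or groups")
    groups <- clade_tip_lists(metadata)
  }
  all_tips <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_tips))
    stop("ambiguous assignment: tip(s) in more than one group: ",
         paste(unique(all_tips[duplicated(all_tips)]), collapse = ", "))
  out <- vector("list", length(groups))
  names(out) <- names(groups)
  for (g in names(groups)) {
    present <- intersect(groups[[g]], tree$phylo$tip.label)
    if (!length(present)) {
      warning("group '", g, "' has no tips in the tree; empty series")
      empty <- slice_rates(tree, from_ma, to_ma, step,
                           scope = character(0), group = g)
      out[[g]] <- empty
      next
    }
    out[[g]] <- slice_rates(tree, from_ma, to_ma, step, scope = present,
                            group = g)
  }
  out
}

#' Export rate series as tidy TSV
#'
#' Columns: group, slice_ma, n_branches, median and (when a trend is
#' supplied) loess_fit.
#'
#' @param series a `rate_series` or named list of them.
#' @param path output file.
#' @param trend optional matching `loess_trend` (or list of them).
#' @return `path`, invisibly.
#' @export
write_rate_series <- function(series, path, trend = NULL) {
  if (inherits(series, "rate_series")) series <- list(series)
  if (!is.null(trend) && inherits(trend, "loess_trend")) trend <- list(trend)
  tabs <- lapply(seq_along(series), function(i) {
    s <- series[[i]]
    df <- data.frame(group = attr(s, "group") %||% names(series)[i],
                     slice_ma = s$slice_ma, n_branches = s$n_branches,
                     median = s$median)
    if (!is.null(trend)) df$loess_fit <- trend[[i]]$fitted
    df
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
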