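#' @name filters
#' @title Link and node filters
#'
#' @description
#' Dense spatial networks are unreadable when every link is drawn, so the
#' pipeline thins the link set before any geometry is computed. Four filters
#' are provided:
#' \itemize{
#'   \item [eco_filter()] — keep the K = round(3N/2) strongest links, i.e.
#'     an average node degree of 3 (the ECO density criterion);
#'   \item [density_filter()] — keep a given proportion or absolute number
#'     of the strongest links;
#'   \item [min_distance_filter()] — keep only links spanning more than a
#'     given physical distance;
#'   \item [top_degree_subnetwork()] — keep the k most connected nodes and
#'     the subnetwork they induce.
#' }
#' All filters return a new `spatial_network` and never alter retained
#' weights or coordinates; symmetry and the zero diagonal are preserved.
#' Ties in weight are broken deterministically: among equal-weight links the
#' one with the smaller (i, j) index pair wins. Each result carries a
#' [filter_report()] describing what was removed.
NULL

#' Retrieve the report attached by the last filter
#'
#' @param net a `spatial_network` returned by one of the filters.
#' @return a list with elements `rule`, `parameter`, `links_before`,
#'   `links_after`, `nodes_before`, `nodes_after`, or `NULL` if `net` has
#'   not been filtered.
#' @export
filter_report <- function(net) attr(net, "filter_report")

#' Format a filter report as a single log line
#' @param report a report from [filter_report()].
#' @return a character scalar.
#' @export
format_filter_report <- function(report) {
  sprintf("filter %s(%s): links %d -> %d, nodes %d -> %d",
          report$rule, paste(format(report$parameter), collapse = ","),
          report$links_before, report$links_after,
          report$nodes_before, report$nodes_after)
}

make_report <- function(rule, parameter, net_before, net_after) {
  list(rule = rule, parameter = parameter,
       links_before = n_links(net_before), links_after = n_links(net_after),
       nodes_before = n_nodes(net_before), nodes_after = n_nodes(net_after))
}

with_report <- function(net, report, log = TRUE) {
  attr(net, "filter_report") <- report
  if (log) message(format_filter_report(report))
  net
}

# links ranked strongest-first, ties by ascending (i, j)
ranked_links <- function(net) {
  lt <- link_table(net)
  lt[order(-lt$weight, lt$i, lt$j), , drop = FALSE]
}

keep_links <- function(net, keep_i, keep_j) {
  w <- matrix(0, n_nodes(net), n_nodes(net))
  w[cbind(keep_i, keep_j)] <- net$weights[cbind(keep_i, keep_j)]
  w[cbind(keep_j, keep_i)] <- net$weights[cbind(keep_j, keep_i)]
  spatial_network(net$coords, w, net$labels)
}

round_half_up <- function(x) floor(x + 0.5)

#' ECO density filter
#'
#' Keeps the K = round(3N/2) largest-weight links (all of them if fewer
#' exist), so that the filtered network has average node degree about 3.
#' The node set is unchanged. The multiplier 3 is exposed as `degree_mult`
#' for users who want a denser or sparser default. A warning is emitted if
#' the filtered network is disconnected; no repair is attempted.
#'
#' @param net a `spatial_network` with at least one link.
#' @param degree_mult target average degree (default 3).
#' @param log emit the one-line filter report as a message.
#' @return the filtered `spatial_network`, with a [filter_report()] attached.
#' @rdname filters
#' @export
eco_filter <- function(net, degree_mult = 3, log = TRUE) {
  stopifnot(inherits(net, "spatial_network"))
  if (n_links(net) < 1L) stop("network has no links", call. = FALSE)
  k <- round_half_up(degree_mult * n_nodes(net) / 2)
  r <- ranked_links(net)
  keep <- r[seq_len(min(k, nrow(r))), , drop = FALSE]
  out <- keep_links(net, keep$i, keep$j)
  if (components_count(out$weights) > 1L)
    warning("ECO-filtered network is disconnected", call. = FALSE)
  with_report(out, make_report("eco", degree_mult, net, out), log)
}

#' Density filter
#'
#' @param keep a proportion in (0, 1] — keep the strongest
#'   `ceiling(keep * L)` links — or a whole number greater than 1, keeping
#'   exactly that many. `keep = 1` means the proportion 1 (identity).
#' @rdname filters
#' @export
density_filter <- function(net, keep, log = TRUE) {
  stopifnot(inherits(net, "spatial_network"))
  l <- n_links(net)
  if (!is.numeric(keep) || length(keep) != 1L || !is.finite(keep) || keep <= 0)
    stop("keep must be a proportion in (0, 1] or a positive link count",
         call. = FALSE)
  if (keep > 1 && keep != floor(keep))
    stop("an absolute link count must be a whole number, got ", keep,
         call. = FALSE)
  k <- if (keep <= 1) ceiling(keep * l) else as.integer(keep)
  if (k > l)
    stop("cannot keep ", k, " links: network has only ", l, call. = FALSE)
  r <- ranked_links(net)
  keep_rows <- r[seq_len(k), , drop = FALSE]
  out <- keep_links(net, keep_rows$i, keep_rows$j)
  with_report(out, make_report("density", keep, net, out), log)
}

#' Minimum-distance filter
#'
#' @param d_min keep only links whose Euclidean internode distance is
#'   strictly greater than `d_min` (in coordinate units).
#' @rdname filters
#' @export
min_distance_filter <- function(net, d_min, log = TRUE) {
  stopifnot(inherits(net, "spatial_network"))
  if (!is.numeric(d_min) || length(d_min) != 1L || !is.finite(d_min) ||
      d_min < 0)
    stop("d_min must be a non-negative length", call. = FALSE)
  lt <- link_table(net)
  keep <- lt[lt$distance > d_min, , drop = FALSE]
  out <- keep_links(net, keep$i, keep$j)
  with_report(out, make_report("min_distance", d_min, net, out), log)
}

#' Top-degree subnetwork
#'
#' @param k number of nodes to keep: the k of largest degree (degree =
#'   incident link count, computed before any removal), ties broken by
#'   ascending node index. Coordinates and labels are re-indexed
#'   consistently and the induced subnetwork returned.
#' @rdname filters
#' @export
top_degree_subnetwork <- function(net, k, log = TRUE) {
  stopifnot(inherits(net, "spatial_network"))
  n <- n_nodes(net)
  if (!is.numeric(k) || length(k) != 1L || k != floor(k) || k < 1 || k > n)
    stop("k must be an integer in [1, ", n, "]", call. = FALSE)
  deg <- node_degrees(net)
  keep <- sort(order(-deg, seq_len(n))[seq_len(k)])
  out <- spatial_network(net$coords[keep, , drop = FALSE],
                         net$weights[keep, keep, drop = FALSE],
                         net$labels[keep])
  with_report(out, make_report("top_degree", k, net, out), log)
}
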