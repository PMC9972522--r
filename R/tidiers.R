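#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a greedy-peel trace
#'
#' One row per candidate subgraph \eqn{H_i} visited by the peeling, with
#' its size and density objective.
#'
#' @param x A `greedy_peel` object.
#' @param ... Unused.
#' @return Tibble with `iteration`, `size`, `objective`.
#' @export
tidy.greedy_peel <- function(x, ...) x$trace

#' @rdname tidy.greedy_peel
#' @return For `glance()`: one row with `c_value`, `objective`, `size`,
#'   `argmax_iteration`.
#' @export
glance.greedy_peel <- function(x, ...) {
  tibble::tibble(c_value = x$c_value, objective = x$objective,
                 size = length(x$node_set), argmax_iteration = x$argmax_iteration)
}

#' Tidy a degree-distribution test
#'
#' @param x A `degree_test` object.
#' @param ... Unused.
#' @return Long tibble with `node`, `network` (`"A"`/`"B"`), `degree`.
#' @export
tidy.degree_test <- function(x, ...) {
  tidyr::pivot_longer(x$degrees, cols = c("degree_a", "degree_b"),
                      names_to = "network", values_to = "degree") |>
    dplyr::mutate(network = ifelse(.data$network == "degree_a", "A", "B"))
}

#' @rdname tidy.degree_test
#' @return For `glance()`: one row with `n_nodes`, `u_statistic`,
#'   `p_value`, `method`.
#' @export
glance.degree_test <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$degrees), u_statistic = x$u_statistic,
                 p_value = x$p_value, method = x$method)
}
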