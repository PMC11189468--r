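#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a model report into per-fold AUROC rows
#'
#' @param x a `model_report`.
#' @param ... unused.
#' @return Tibble: `group`, `model` (`"panel"` / `"clinical"`), `index`
#'   (fold position in repeat-major order), `auroc`.
#' @export
#' @method tidy model_report
tidy.model_report <- function(x, ...) {
  mk <- function(scores, model) {
    tibble::tibble(group = x$group, model = model,
                   index = seq_along(scores), auroc = scores)
  }
  out <- mk(x$fold_scores, "panel")
  if (!is.null(x$comparator_fold_scores)) {
    out <- dplyr::bind_rows(out, mk(x$comparator_fold_scores, "clinical"))
  }
  out
}

#' @rdname tidy.model_report
#' @export
#' @method glance model_report
glance.model_report <- function(x, ...) {
  tibble::tibble(group = x$group, n = x$n, n_features = x$n_features,
                 auroc_mean = x$auroc_mean, auroc_sd = x$auroc_sd,
                 comparator_auroc_mean = x$comparator_auroc_mean,
                 comparator_auroc_sd = x$comparator_auroc_sd)
}

#' Tidy methods for endotype groups and mapper objects
#'
#' @param x an `endotype_groups`, `mapper_graph` or `stepup_curve`.
#' @param ... unused.
#' @return A tibble (one row per patient, node/edge, or panel size).
#' @export
#' @method tidy endotype_groups
tidy.endotype_groups <- function(x, ...) {
  tibble::tibble(patient_id = names(x$exclusive),
                 group = unname(x$exclusive),
                 shared = unname(x$exclusive) == "shared")
}

#' @rdname tidy.endotype_groups
#' @export
#' @method glance endotype_groups
glance.endotype_groups <- function(x, ...) {
  tibble::tibble(n_groups = length(x$groups),
                 n_patients = length(x$exclusive),
                 n_shared = sum(x$exclusive == "shared"),
                 shared_fraction = x$shared_fraction)
}

#' @rdname tidy.endotype_groups
#' @export
#' @method tidy mapper_graph
tidy.mapper_graph <- function(x, ...) {
  dplyr::select(x$nodes, "node", "bin", "size")
}

#' @rdname tidy.endotype_groups
#' @export
#' @method glance mapper_graph
glance.mapper_graph <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 n_patients = length(unique(unlist(x$nodes$patients))))
}

#' @rdname tidy.endotype_groups
#' @export
#' @method tidy stepup_curve
tidy.stepup_curve <- function(x, ...) x$curve

#' @rdname tidy.endotype_groups
#' @export
#' @method glance stepup_curve
glance.stepup_curve <- function(x, ...) {
  best <- which.max(x$curve$auroc_mean)
  tibble::tibble(n_star = x$n_star,
                 auroc_at_n_star = x$curve$auroc_mean[x$curve$n == x$n_star],
                 best_n = x$curve$n[best], best_auroc = x$curve$auroc_mean[best])
}
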