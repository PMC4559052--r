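#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-locus F-statistics
#' @param x A [wc_fstats()] object.
#' @param ... Unused.
#' @return Tibble with one row per locus (components and F-statistics).
#' @method tidy wc_fstats
#' @export
tidy.wc_fstats <- function(x, ...) x$per_locus

#' One-row summary of an F-statistics fit
#' @param x A [wc_fstats()] object.
#' @param ... Unused.
#' @method glance wc_fstats
#' @export
glance.wc_fstats <- function(x, ...) {
  tibble::tibble(fis = x$overall$fis, fst = x$overall$fst,
                 fit = x$overall$fit, p_fis = x$p_fis, p_fst = x$p_fst,
                 n_perm = x$n_perm, grouping = x$grouping)
}

#' Tidy AMOVA components
#' @param x An [amova()] object.
#' @param ... Unused.
#' @method tidy amova
#' @export
tidy.amova <- function(x, ...) x$components

#' One-row AMOVA summary
#' @param x An [amova()] object.
#' @param ... Unused.
#' @method glance amova
#' @export
glance.amova <- function(x, ...) {
  tibble::tibble(phi_st = x$phi$phi_st, phi_is = x$phi$phi_is,
                 phi_it = x$phi$phi_it,
                 p_among_colonies = x$p_among_colonies,
                 p_within_colonies = x$p_within_colonies,
                 n_perm = x$n_perm)
}

#' Tidy sPCA axes
#' @param x An [spca()] object.
#' @param ... Unused.
#' @return Tibble `axis`, `lambda`, `variance`, `moran_i`.
#' @method tidy spca
#' @export
tidy.spca <- function(x, ...) x$axes

#' One-row sPCA summary
#' @param x An [spca()] object.
#' @param ... Unused.
#' @method glance spca
#' @export
glance.spca <- function(x, ...) {
  tibble::tibble(lambda_1 = x$eigenvalues[1],
                 lambda_2 = x$eigenvalues[2],
                 moran_i_1 = x$axes$moran_i[1],
                 prop_first_two = sum(abs(x$eigenvalues[1:2])) /
                   sum(abs(x$eigenvalues)))
}

#' Tidy admixture proportions
#' @param x A [gibbs_admixture()] fit.
#' @param ... Unused.
#' @return Long tibble `individual_id`, `colony_id`, `cluster`, `q`.
#' @method tidy admix_fit
#' @export
tidy.admix_fit <- function(x, ...) {
  tibble::tibble(
    individual_id = rep(rownames(x$q), times = x$k),
    colony_id = rep(x$colony, times = x$k),
    cluster = rep(colnames(x$q), each = nrow(x$q)),
    q = as.vector(x$q))
}

#' One-row admixture-fit summary
#' @param x A [gibbs_admixture()] fit.
#' @param ... Unused.
#' @method glance admix_fit
#' @export
glance.admix_fit <- function(x, ...) {
  tibble::tibble(k = x$k, lhat = x$lhat, mean_lnl = mean(x$lnl),
                 var_lnl = var(x$lnl), sweeps = length(x$lnl))
}

#' Tidy the Delta-K table
#' @param x An [evanno_deltak()] object.
#' @param ... Unused.
#' @method tidy deltak
#' @export
tidy.deltak <- function(x, ...) x$table

#' One-row Delta-K summary
#' @param x An [evanno_deltak()] object.
#' @param ... Unused.
#' @method glance deltak
#' @export
glance.deltak <- function(x, ...) {
  tibble::tibble(selected_k = x$selected_k,
                 max_delta_k = suppressWarnings(
                   max(x$table$delta_k, na.rm = TRUE)))
}
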