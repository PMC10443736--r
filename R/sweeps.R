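#' Evaluate model quantities at new parameter values
#'
#' Evaluates one or more diffusion quantities at parameter points derived
#' from the model by row-wise overrides.  This is the engine behind
#' [run_sweep()].
#'
#' @param object A [phasesel] model.
#' @param newdata Optional data frame of parameter overrides (columns
#'   named after [phasesel()] arguments, one row per evaluation point).
#'   `NULL` evaluates the model as is.
#' @param type Character vector of requested quantities among
#'   `"ka_ks"`, `"phi"`, `"phi0"`, `"pi_a"`, `"pi_s"`, `"pi_ratio"`.
#' @param ... Unused.
#' @return A data frame with the override columns, one column per
#'   requested quantity (`NA` where a regime does not admit it), and a
#'   `status` flag: `"ok"`, `"nonintegrable"` (migration too strong for
#'   the fixation integrals) or `"transient-polymorphism"` (`mtilde = 0`,
#'   no stationary density).
#' @examples
#' m <- phasesel(sh = 0.03, N = 30)
#' predict(m, data.frame(alpha = c(0, 0.5, 1)), type = "ka_ks")
#' @export
predict.phasesel <- function(object, newdata = NULL,
                             type = "ka_ks", ...) {
  type <- match.arg(type, c("ka_ks", "phi", "phi0", "pi_a", "pi_s",
                            "pi_ratio"), several.ok = TRUE)
  if (is.null(newdata)) newdata <- data.frame(row.names = 1)
  nrows <- max(nrow(newdata), 1L)
  res <- newdata
  for (ty in type) res[[ty]] <- NA_real_
  res$status <- "ok"
  for (i in seq_len(nrows)) {
    over <- as.list(newdata[i, , drop = FALSE])
    m <- tryCatch(do.call(modify_model, c(list(object), over)),
                  error = function(e) e)
    if (inherits(m, "error")) { res$status[i] <- conditionMessage(m); next }
    rate_needed <- any(c("ka_ks", "phi", "phi0") %in% type)
    if (rate_needed) {
      r <- tryCatch(ka_ks(m), error = function(e) e)
      if (inherits(r, "error")) {
        res$status[i] <- if (grepl("nonintegrable", conditionMessage(r)))
          "nonintegrable" else conditionMessage(r)
      } else {
        if ("ka_ks" %in% type) res$ka_ks[i] <- r$ka_ks
        if ("phi" %in% type) res$phi[i] <- r$phi
        if ("phi0" %in% type) res$phi0[i] <- r$phi0
      }
    }
    if (any(c("pi_a", "pi_ratio") %in% type)) {
      if (m$derived$mtilde > 0) {
        pa <- pi_a(m)
        ps <- pi_s(m)
        if ("pi_a" %in% type) res$pi_a[i] <- pa$pi_a
        if ("pi_ratio" %in% type) res$pi_ratio[i] <- pa$pi_a / ps$pi_s
      } else if (res$status[i] == "ok")
        res$status[i] <- "transient-polymorphism"
    }
    if ("pi_s" %in% type) {
      ps <- pi_s(m)
      res$pi_s[i] <- ps$pi_s
      if (ps$transient && res$status[i] == "ok")
        res$status[i] <- "transient-polymorphism"
    }
  }
  res
}

#' Run a one-parameter sweep
#'
#' Evaluates the requested quantities over an ordered grid of one
#' parameter, with per-row status flags (never silent omissions) and a
#' monotonicity summary.
#'
#' @param object A [phasesel] base model.
#' @param axis Parameter to vary: one of `"alpha"`, `"mP"`, `"mS"`,
#'   `"N"`, `"sh"`, `"sd"`, `"h"`.
#' @param grid Strictly monotone numeric grid of axis values.
#' @param outputs Quantities to compute (see [predict.phasesel()]).
#' @param track_p0 If `TRUE` (default) and the axis is `N`, the initial
#'   frequency follows `p0 = 1/(2N)` along the grid, the convention of a
#'   single new mutant copy.
#' @return A data frame of class `"phasesel_sweep"` with the axis column,
#'   requested quantities and `status`; attributes `axis` and
#'   `monotonicity` (per-quantity summary `"increasing"`,
#'   `"decreasing"`, `"constant"` or `"turning"`).
#' @examples
#' m <- phasesel(sh = 0.03, N = 30, p0 = 1/60)
#' run_sweep(m, "alpha", seq(0, 1, by = 0.25))
#' @export
run_sweep <- function(object, axis, grid,
                      outputs = "ka_ks", track_p0 = TRUE) {
  axis <- match.arg(axis, c("alpha", "mP", "mS", "N", "sh", "sd", "h"))
  stopifnot(length(grid) >= 1, !is.unsorted(grid) || !is.unsorted(rev(grid)))
  if (length(grid) > 1 && any(diff(grid) == 0))
    stop("sweep grid must be strictly monotone", call. = FALSE)
  nd <- stats::setNames(data.frame(grid), axis)
  if (axis == "N" && track_p0) nd$p0 <- 1 / (2 * grid)
  res <- predict(object, nd, type = outputs)
  mono <- lapply(outputs, function(q) {
    v <- res[[q]][res$status == "ok" & !is.na(res[[q]])]
    if (length(v) < 2) return("constant")
    dv <- diff(v)
    if (all(dv >= -1e-12)) "increasing"
    else if (all(dv <= 1e-12)) "decreasing"
    else "turning"
  })
  structure(res, class = c("phasesel_sweep", "data.frame"),
            axis = axis, monotonicity = stats::setNames(mono, outputs),
            base = object)
}

#' @export
print.phasesel_sweep <- function(x, ...) {
  cat("Parameter sweep over", attr(x, "axis"), "(", nrow(x), "points )\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  mono <- attr(x, "monotonicity")
  cat("monotonicity:",
      paste(names(mono), unlist(mono), sep = ": ", collapse = "; "), "\n")
  flagged <- sum(x$status != "ok")
  if (flagged > 0) cat(flagged, "row(s) flagged (see status column)\n")
  invisible(x)
}

#' Plot a parameter sweep
#'
#' Base-graphics line plot of each computed quantity against the sweep
#' axis; flagged rows are omitted from the lines and marked on the axis.
#'
#' @param x A `"phasesel_sweep"` result.
#' @param ... Passed to [plot()].
#' @export
plot.phasesel_sweep <- function(x, ...) {
  axis_nm <- attr(x, "axis")
  qs <- setdiff(names(x), c(axis_nm, "p0", "status"))
  ok <- x$status == "ok"
  op <- graphics::par(mfrow = c(1, length(qs)))
  on.exit(graphics::par(op))
  for (q in qs) {
    graphics::plot(x[[axis_nm]][ok], x[[q]][ok], type = "l",
                   xlab = axis_nm, ylab = q, ...)
    if (any(!ok))
      graphics::rug(x[[axis_nm]][!ok], col = "red")
  }
  invisible(x)
}

#' Figure-style parameter settings
#'
#' Ready-made base models and sweep specifications reproducing the
#' numerical-example settings used to illustrate the theory: selfing-rate
#' sweeps under gametophytic-only, sporophytic-only and biphasic
#' selection with additive or extreme dominance, pollen-flow sweeps, and
#' population-size sweeps.  All use `N = 30`, `p0 = 1/(2N)` and, for the
#' migration settings, `Qa = 0.5` with predominant outcrossing
#' (`alpha = 0.05`).
#'
#' @param figure One of `"fig2"` (gametophytic selection, `sh` 0.03 or
#'   0.06, alpha sweep), `"fig3"` (antagonistic one- and biphasic
#'   settings, alpha sweep), `"fig4"` (dominance `h` 0 vs 1,
#'   sporophytic-only, alpha sweep), `"fig5"` (dominance under
#'   synergistic biphasic selection, alpha sweep), `"fig6"` (pollen-flow
#'   sweep), `"fig7"` (population-size sweep).
#' @param points Grid resolution (default 51).
#' @return A list of sweep specifications, each with components `model`,
#'   `axis`, `grid`, `outputs` and `label`, directly runnable via
#'   [run_sweep()].
#' @examples
#' sp <- figure_settings("fig2")[[1]]
#' run_sweep(sp$model, sp$axis, sp$grid, sp$outputs)
#' @export
figure_settings <- function(figure = c("fig2", "fig3", "fig4", "fig5",
                                       "fig6", "fig7"),
                            points = 51) {
  figure <- match.arg(figure)
  N <- 30
  p0 <- 1 / (2 * N)
  agrid <- seq(0, 1, length.out = points)
  spec <- function(model, axis, grid, outputs, label)
    list(model = model, axis = axis, grid = grid, outputs = outputs,
         label = label)
  base <- function(scheme, sh, sd, h, alpha = 0, mP = 0, mS = 0)
    phasesel(scheme, sh = sh, sd = sd, h = h, alpha = alpha, N = N,
             mP = mP, mS = mS, Qa = 0.5, p0 = p0)
  switch(figure,
    fig2 = lapply(c(0.03, 0.06), function(s)
      spec(base("antagonistic", s, 0, 0.5), "alpha", agrid, "ka_ks",
           sprintf("gametophytic sh=%g", s))),
    fig3 = list(
      spec(base("antagonistic", 0.03, 0, 0.5), "alpha", agrid, "ka_ks",
           "gametophytic sh=0.03"),
      spec(base("antagonistic", 0, 0.05, 0.5), "alpha", agrid, "ka_ks",
           "sporophytic sd=0.05"),
      spec(base("antagonistic", 0.03, 0.05, 0.5), "alpha", agrid, "ka_ks",
           "biphasic sh=0.03 sd=0.05")),
    fig4 = lapply(c(0, 1), function(hh)
      spec(base("antagonistic", 0, 0.05, hh), "alpha", agrid, "ka_ks",
           sprintf("sporophytic-only h=%g", hh))),
    fig5 = lapply(c(0, 1), function(hh)
      spec(base("synergistic", 0.03, 0.05, hh), "alpha", agrid, "ka_ks",
           sprintf("synergistic biphasic h=%g", hh))),
    fig6 = {
      mgrid <- seq(0, 0.1, length.out = points)
      list(
        spec(base("antagonistic", 0.03, 0, 0.5, alpha = 0.05), "mP",
             mgrid, c("ka_ks", "pi_a", "pi_ratio"),
             "gametophytic sh=0.03"),
        spec(base("antagonistic", 0, 0.05, 0.5, alpha = 0.05), "mP",
             mgrid, c("ka_ks", "pi_a", "pi_ratio"),
             "sporophytic sd=0.05"),
        spec(base("antagonistic", 0.03, 0.05, 0.5, alpha = 0.05), "mP",
             mgrid, c("ka_ks", "pi_a", "pi_ratio"),
             "biphasic sh=0.03 sd=0.05"))
    },
    fig7 = {
      Ngrid <- round(seq(10, 100, length.out = min(points, 46)))
      Ngrid <- Ngrid[!duplicated(Ngrid)]
      list(
        spec(base("antagonistic", 0.03, 0, 0.5, alpha = 0.05), "N",
             Ngrid, "ka_ks", "gametophytic sh=0.03"),
        spec(base("antagonistic", 0, 0.05, 0.5, alpha = 0.05), "N",
             Ngrid, "ka_ks", "sporophytic sd=0.05"),
        spec(base("antagonistic", 0.03, 0.05, 0.5, alpha = 0.05), "N",
             Ngrid, "ka_ks", "biphasic sh=0.03 sd=0.05"))
    })
}

#' Read a model from a YAML or JSON configuration file
#'
#' Configuration keys mirror the [phasesel()] arguments one-to-one; all
#' are optional and missing keys take the constructor defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [phasesel] model.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  # YAML 1.1 reads a bare `N:` key as boolean FALSE; map it back
  names(cfg)[names(cfg) %in% c("FALSE", "no")] <- "N"
  known <- names(formals(phasesel))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(phasesel, cfg)
}

#' Write a model's parameters to a configuration file
#'
#' @param object A [phasesel] model.
#' @param path Output path; format chosen by extension (`.yaml`/`.yml`
#'   or `.json`).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(object, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(object$params, path)
  else jsonlite::write_json(object$params, path, auto_unbox = TRUE,
                            digits = NA)
  invisible(path)
}
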