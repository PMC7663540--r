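# Two-level polar chart of a fitted component model ("multi-level polar
# chart"): one equal-angle sector per selected component, sector radius
# proportional to |Cox coefficient| (sign encoded by fill), containing one
# point per nonzero-loading variable at radial distance proportional to
# |loading| (sign encoded by marker shape/fill). Geometry is computed into
# a plain spec object first; rendering is a pure function of the spec.

#' Build the geometry of a multi-level polar chart
#'
#' Sectors are sorted by descending `|coefficient|` (ties broken by label)
#' and laid out clockwise from 12 o'clock with equal angular width
#' `2*pi/K`. Sector radius is `|b_k| / max|b_k|`, so the geometry is
#' invariant to rescaling all coefficients. Each nonzero-loading variable
#' becomes a point at radius `min(|loading|, 1) * sector radius`, with a
#' seeded uniform angular jitter inside the middle 80% of its sector so
#' coincident loadings stay distinguishable.
#'
#' @param fit a `cox_fit` with at least one selected component.
#' @param provenance provenance map (`$provenance` of the
#'   `integrated_dataset`), with nonzero loadings for every fitted label.
#' @param seed integer seed for the angular jitter.
#' @return an object of class `mpchart_spec`: `sectors` (data frame:
#'   `label`, `start`, `end`, `radius`, `sign`) and `points` (data frame:
#'   `sector`, `variable`, `radius`, `angle`, `sign`), plus `K` and
#'   `seed`.
#' @export
build_mpchart_spec <- function(fit, provenance, seed = 1L) {
  stopifnot(inherits(fit, "cox_fit"))
  if (length(fit$labels) == 0) stop("the fitted model has no components to draw")
  missing <- setdiff(fit$labels, names(provenance))
  if (length(missing))
    stop("provenance missing loadings for: ", paste(missing, collapse = ", "))

  co <- fit$coefficients
  ord <- order(-abs(co), fit$labels)
  labels <- fit$labels[ord]
  co <- co[ord]
  K <- length(labels)
  width <- 2 * pi / K
  # clockwise from 12 o'clock: sector k spans [(k-1)*w, k*w] measured
  # clockwise from the top
  start <- (seq_len(K) - 1) * width
  radius <- abs(co) / max(abs(co))
  sectors <- data.frame(label = labels, start = start, end = start + width,
                        radius = unname(radius),
                        sign = ifelse(co >= 0, 1L, -1L))

  rng <- make_rng(seed)
  pts <- do.call(rbind, lapply(seq_len(K), function(k) {
    pv <- provenance[[labels[k]]]
    ld <- pv$loadings
    if (length(ld) == 0) stop("component ", labels[k], " has no nonzero loadings")
    jit <- vapply(seq_along(ld), function(i) rng(), numeric(1))
    # middle 80% of the sector
    ang <- start[k] + width * (0.1 + 0.8 * jit)
    data.frame(sector = labels[k], variable = names(ld),
               radius = pmin(abs(unname(ld)), 1) * radius[[k]],
               angle = ang, sign = ifelse(unname(ld) >= 0, 1L, -1L))
  }))
  structure(list(sectors = sectors, points = pts, K = K, seed = as.integer(seed)),
            class = "mpchart_spec")
}

# small deterministic generator (linear congruential), independent of the
# global .Random.seed so chart jitter never perturbs analysis streams
make_rng <- function(seed) {
  state <- as.double(as.integer(seed) %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  function() {
    state <<- (state * 16807) %% 2147483647
    state / 2147483647
  }
}

#' @export
print.mpchart_spec <- function(x, ...) {
  cat(sprintf("mpchart_spec: %d sectors, %d variable points (seed %d)\n",
              x$K, nrow(x$points), x$seed))
  invisible(x)
}

#' Serialize a chart spec to JSON
#' @param spec an `mpchart_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mpchart_spec <- function(spec, path) {
  stopifnot(inherits(spec, "mpchart_spec"))
  jsonlite::write_json(list(K = spec$K, seed = spec$seed,
                            sectors = spec$sectors, points = spec$points),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Rebuild and render a chart from exported run artifacts
#'
#' Reads a model summary JSON (as written by [run_pipeline()]) and a
#' long-format loadings TSV, rebuilds the chart spec and renders it.
#'
#' @param model_path path to `model.json` (`labels`, `coefficients`).
#' @param loadings_path path to `loadings.tsv` (`component`, `variable`,
#'   `loading`).
#' @param out_path output `.svg` path.
#' @param seed jitter seed.
#' @return the `mpchart_spec`, invisibly.
#' @export
mpchart_from_files <- function(model_path, loadings_path, out_path, seed = 1L) {
  model <- jsonlite::read_json(model_path)
  labels <- unlist(model$labels)
  co <- stats::setNames(vapply(model$coefficients[labels], as.numeric,
                               numeric(1)), labels)
  fit <- structure(list(labels = labels, coefficients = co,
                        se = rep(NA_real_, length(co)),
                        hazard_ratios = exp(co),
                        p_values = rep(NA_real_, length(co)),
                        loglik = NA_real_, aic = model$aic %||% NA_real_,
                        n = NA_integer_, n_events = NA_integer_,
                        ties = "efron", fit = NULL),
                   class = "cox_fit")
  ld <- utils::read.delim(loadings_path)
  prov <- lapply(split(ld, ld$component), function(d)
    list(layer_id = NA_character_, block_index = NA_integer_,
         block_size = nrow(d), support = d$variable,
         loadings = stats::setNames(d$loading, d$variable)))
  spec <- build_mpchart_spec(fit, prov[labels], seed = seed)
  render_mpchart(spec, out_path)
  invisible(spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# polar (clockwise-from-top angle, radius in [0,1]) -> SVG canvas x,y
polar_xy <- function(angle, radius, cx, cy, scale) {
  list(x = cx + scale * radius * sin(angle),
       y = cy - scale * radius * cos(angle))
}

fmt <- function(x) sprintf("%.4f", x)

#' Render a multi-level polar chart to SVG
#'
#' Pure function of the spec: the same spec always yields byte-identical
#' output. Positive-coefficient sectors are filled light grey, negative
#' ones white; positive loadings are filled dark triangles, negative ones
#' open circles.
#'
#' @param spec an `mpchart_spec`.
#' @param path output `.svg` path.
#' @param size canvas size in pixels (square).
#' @return `path`, invisibly.
#' @export
render_mpchart <- function(spec, path, size = 600) {
  stopifnot(inherits(spec, "mpchart_spec"))
  if (nrow(spec$sectors) == 0) stop("empty sector list")
  cx <- size / 2; cy <- size / 2
  scale <- 0.38 * size
  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d"',
                          ' height="%d" viewBox="0 0 %d %d">'),
                   size, size, size, size),
           sprintf('<circle cx="%s" cy="%s" r="%s" fill="none" stroke="#888" stroke-width="1"/>',
                   fmt(cx), fmt(cy), fmt(scale)))
  for (i in seq_len(nrow(spec$sectors))) {
    s <- spec$sectors[i, ]
    a0 <- polar_xy(s$start, s$radius, cx, cy, scale)
    a1 <- polar_xy(s$end, s$radius, cx, cy, scale)
    large <- if ((s$end - s$start) > pi) 1 else 0
    fill <- if (s$sign > 0) "#c8c8c8" else "#ffffff"
    if (spec$K == 1) {
      # a single sector is the full disc
      out <- c(out, sprintf(
        '<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="#444" stroke-width="1"/>',
        fmt(cx), fmt(cy), fmt(scale * s$radius), fill))
    } else {
      out <- c(out, sprintf(
        '<path d="M %s %s L %s %s A %s %s 0 %d 1 %s %s Z" fill="%s" stroke="#444" stroke-width="1"/>',
        fmt(cx), fmt(cy), fmt(a0$x), fmt(a0$y),
        fmt(scale * s$radius), fmt(scale * s$radius), large,
        fmt(a1$x), fmt(a1$y), fill))
    }
    mid <- polar_xy((s$start + s$end) / 2, 1.08, cx, cy, scale)
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="14" font-family="sans-serif" text-anchor="middle">%s</text>',
      fmt(mid$x), fmt(mid$y), s$label))
  }
  for (i in seq_len(nrow(spec$points))) {
    p <- spec$points[i, ]
    xy <- polar_xy(p$angle, p$radius, cx, cy, scale)
    if (p$sign > 0) {
      r <- 4
      out <- c(out, sprintf(
        '<polygon points="%s,%s %s,%s %s,%s" fill="#222222"/>',
        fmt(xy$x), fmt(xy$y - r), fmt(xy$x - r), fmt(xy$y + r),
        fmt(xy$x + r), fmt(xy$y + r)))
    } else {
      out <- c(out, sprintf(
        '<circle cx="%s" cy="%s" r="3.5" fill="#ffffff" stroke="#222222" stroke-width="1.2"/>',
        fmt(xy$x), fmt(xy$y)))
    }
  }
  leg_y <- size - 24
  out <- c(out,
           sprintf('<polygon points="%s,%s %s,%s %s,%s" fill="#222222"/>',
                   fmt(20), fmt(leg_y - 4), fmt(16), fmt(leg_y + 4), fmt(24), fmt(leg_y + 4)),
           sprintf('<text x="30" y="%s" font-size="12" font-family="sans-serif" dominant-baseline="middle">positive loading</text>', fmt(leg_y)),
           sprintf('<circle cx="160" cy="%s" r="3.5" fill="#ffffff" stroke="#222222" stroke-width="1.2"/>', fmt(leg_y)),
           sprintf('<text x="170" y="%s" font-size="12" font-family="sans-serif" dominant-baseline="middle">negative loading</text>', fmt(leg_y)),
           sprintf('<rect x="300" y="%s" width="10" height="10" fill="#c8c8c8" stroke="#444"/>', fmt(leg_y - 5)),
           sprintf('<text x="316" y="%s" font-size="12" font-family="sans-serif" dominant-baseline="middle">coefficient &#8805; 0</text>', fmt(leg_y)),
           sprintf('<rect x="430" y="%s" width="10" height="10" fill="#ffffff" stroke="#444"/>', fmt(leg_y - 5)),
           sprintf('<text x="446" y="%s" font-size="12" font-family="sans-serif" dominant-baseline="middle">coefficient &lt; 0</text>', fmt(leg_y)),
           '</svg>')
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}
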