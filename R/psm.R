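#' Compare measurement groups
#'
#' Two groups are compared by an unpaired two-sided t-test; three or more by
#' one-way ANOVA followed by all-pairs post-hoc comparisons that feed the
#' pairwise significance matrix. The default post-hoc procedure is pairwise
#' Welch t-tests without multiplicity correction — the literal reading of a
#' flat `p < 0.05` criterion — with Holm correction and Tukey's HSD
#' available.
#'
#' @param values named list of numeric vectors (one per group), or a
#'   data.frame with columns `group` and `value`.
#' @param correction `"none"` (default), `"holm"`, or `"tukey"`.
#' @param var_equal use pooled-variance t-tests instead of Welch.
#' @param alpha significance level (default 0.05, strict `p < alpha`).
#' @return a `group_comparison`: list with `groups`, `omnibus`
#'   (test name, statistic, p), and `pairs` (data.frame `group1`, `group2`,
#'   `p_value`, `significant`).
#' @export
compare_groups <- function(values, correction = c("none", "holm", "tukey"),
                           var_equal = FALSE, alpha = 0.05) {
  correction <- match.arg(correction)
  if (is.data.frame(values)) {
    stopifnot(all(c("group", "value") %in% names(values)))
    values <- split(values$value, values$group)
  }
  if (length(values) < 2) stop("need at least 2 groups")
  if (any(vapply(values, length, 0L) < 2))
    stop("each group needs at least 2 observations")
  if (all(vapply(values, function(v) sd(v) == 0, TRUE)))
    stop("zero within-group variance in every group; tests are undefined")
  groups <- names(values) %||% paste0("group", seq_along(values))
  names(values) <- groups

  if (length(values) == 2) {
    tt <- t.test(values[[1]], values[[2]], var.equal = var_equal)
    pairs <- data.frame(group1 = groups[1], group2 = groups[2],
                        p_value = tt$p.value,
                        significant = tt$p.value < alpha)
    omnibus <- list(test = "t", statistic = unname(tt$statistic),
                    p_value = tt$p.value)
  } else {
    df <- data.frame(value = unlist(values, use.names = FALSE),
                     group = factor(rep(groups,
                                        vapply(values, length, 0L)),
                                    levels = groups))
    fit <- aov(value ~ group, data = df)
    an <- summary(fit)[[1]]
    omnibus <- list(test = "anova", statistic = an[["F value"]][1],
                    p_value = an[["Pr(>F)"]][1])
    cmb <- utils::combn(groups, 2)
    if (correction == "tukey") {
      tk <- TukeyHSD(fit)$group
      key <- paste(cmb[2, ], cmb[1, ], sep = "-")
      p <- tk[match(key, rownames(tk)), "p adj"]
    } else {
      p <- apply(cmb, 2, function(g)
        t.test(values[[g[1]]], values[[g[2]]],
               var.equal = var_equal)$p.value)
      if (correction == "holm") p <- p.adjust(p, "holm")
    }
    pairs <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                        p_value = unname(p), significant = p < alpha)
  }
  structure(list(groups = groups, omnibus = omnibus, pairs = pairs,
                 alpha = alpha, correction = correction),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", length(x$groups), " groups | omnibus ",
      x$omnibus$test, " p = ", signif(x$omnibus$p_value, 3), "\n", sep = "")
  print(x$pairs)
  invisible(x)
}

#' Build a pairwise significance matrix
#'
#' Arranges per-pair comparison outcomes into the symmetric green/red box
#' matrix used to summarize longitudinal group comparisons: green = the
#' pair differs significantly (strictly `p < alpha`), red = it does not.
#'
#' @param comparison a `group_comparison` from [compare_groups()], or a
#'   data.frame with columns `group1`, `group2`, `p_value`.
#' @param groups group order for rendering (default: order of appearance).
#' @param alpha significance level (default 0.05).
#' @return a `psm`: list with `groups`, symmetric numeric `p` matrix
#'   (diagonal `NA`), logical `significant` matrix, and `alpha`. Errors if
#'   any unordered pair is missing.
#' @export
build_psm <- function(comparison, groups = NULL, alpha = 0.05) {
  pairs <- if (inherits(comparison, "group_comparison")) comparison$pairs
           else as.data.frame(comparison)
  stopifnot(all(c("group1", "group2", "p_value") %in% names(pairs)))
  groups <- groups %||% (if (inherits(comparison, "group_comparison"))
    comparison$groups else unique(c(pairs$group1, pairs$group2)))
  k <- length(groups)
  p <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$group1[i]; b <- pairs$group2[i]
    if (!a %in% groups || !b %in% groups) next
    p[a, b] <- p[b, a] <- pairs$p_value[i]
  }
  if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    if (is.na(p[i, j]))
      stop("missing comparison for pair ", groups[i], " vs ", groups[j])
  }
  structure(list(groups = groups, p = p, significant = p < alpha,
                 alpha = alpha), class = "psm")
}

#' Look up one pair in a significance matrix
#'
#' Symmetric: `psm_lookup(m, a, b)` equals `psm_lookup(m, b, a)`.
#'
#' @param psm a `psm` object.
#' @param a,b group names.
#' @return list with `p_value` and `significant`.
#' @export
psm_lookup <- function(psm, a, b) {
  stopifnot(inherits(psm, "psm"))
  if (!a %in% psm$groups || !b %in% psm$groups)
    stop("unknown group in lookup")
  if (a == b) stop("the diagonal of a PSM is undefined")
  list(p_value = psm$p[a, b], significant = psm$significant[a, b])
}

#' @export
print.psm <- function(x, ...) {
  cat("<psm> alpha =", x$alpha, "\n")
  m <- ifelse(is.na(x$p), ".", ifelse(x$significant, "green", "red"))
  print(m, quote = FALSE)
  invisible(x)
}

#' Write a PSM as JSON and as an SVG box rendering
#'
#' The SVG shows one box per unordered pair (upper triangle), green for a
#' significant difference, red for a non-significant one.
#'
#' @param psm a `psm` object.
#' @param json_path,svg_path output paths (`NULL` to skip either).
#' @return invisible list of the paths written.
#' @export
write_psm <- function(psm, json_path = NULL, svg_path = NULL) {
  stopifnot(inherits(psm, "psm"))
  if (!is.null(json_path)) {
    cmb <- utils::combn(psm$groups, 2)
    comps <- lapply(seq_len(ncol(cmb)), function(i) list(
      group1 = cmb[1, i], group2 = cmb[2, i],
      p_value = psm$p[cmb[1, i], cmb[2, i]],
      significant = psm$significant[cmb[1, i], cmb[2, i]]))
    jsonlite::write_json(list(alpha = psm$alpha, groups = psm$groups,
                              comparisons = comps),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(svg_path)) {
    k <- length(psm$groups)
    cell <- 40; pad <- 110
    wdt <- pad + k * cell + 10; hgt <- pad + k * cell + 10
    lines <- c(sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
      wdt, hgt))
    for (i in seq_len(k)) {
      lines <- c(lines, sprintf(
        '<text x="%d" y="%f" font-size="12" text-anchor="end">%s</text>',
        pad - 6, pad + (i - 0.4) * cell, psm$groups[i]), sprintf(
        '<text x="%f" y="%d" font-size="12" transform="rotate(-45 %f %d)">%s</text>',
        pad + (i - 0.7) * cell, pad - 8, pad + (i - 0.7) * cell, pad - 8,
        psm$groups[i]))
      for (j in seq_len(k)) {
        if (j <= i) next
        col <- if (isTRUE(psm$significant[i, j])) "#2ca02c" else "#d62728"
        lines <- c(lines, sprintf(
          '<rect x="%d" y="%d" width="%d" height="%d" fill="%s" stroke="black"/>',
          pad + (j - 1) * cell, pad + (i - 1) * cell, cell, cell, col))
      }
    }
    writeLines(c(lines, "</svg>"), svg_path)
  }
  invisible(list(json = json_path, svg = svg_path))
}
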