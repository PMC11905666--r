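#' Independently verify an anonymized dataset
#'
#' A self-contained verifier, implemented separately from the
#' anonymization engine, that re-derives the equivalence classes of an
#' output dataset and re-evaluates every configured privacy model from
#' its definition.  It shares no code with the lattice-search or
#' compliance machinery, so it can serve as an independent check that the
#' merged output of a partition-parallel run satisfies the configured
#' guarantees under the global reference distribution.
#'
#' Rows with `"*"` in every quasi-identifier cell are treated as
#' suppressed and excluded from all risk computations.  The reference
#' distribution defaults to the distribution of the output's sensitive
#' columns, which anonymization leaves untouched, so it equals the input
#' distribution.
#'
#' @param output An anonymized dataset (tibble).
#' @param config The [anon_config()] the output was produced under.
#' @param ref Optional [reference_stats()]; defaults to the sensitive
#'   distribution of `output` itself (all rows).
#' @return A `privacy_check` object: `pass` (overall), `models` (tibble
#'   with one row per configured model: `model`, `level`, `monotonic`,
#'   `pass`, `worst` — the model's worst observed statistic),
#'   `n_records`, `n_suppressed`, `n_classes`.
#' @examples
#' syn <- generate_dataset(100, qi_domains = c(5, 5), seed = 2)
#' cfg <- anon_config(syn$quasi_identifiers, syn$hierarchies,
#'                    sensitive = syn$sensitive,
#'                    models = list(k_anonymity(3)))
#' fit <- run_p4(syn$data, cfg, partitions = 2)
#' check_privacy(fit$output, cfg)$pass
#' @export
check_privacy <- function(output, config, ref = NULL) {
  stopifnot(inherits(config, "anon_config"))
  qis <- config$quasi_identifiers
  n <- nrow(output)

  ## reference distributions (plain named vectors)
  refd <- if (is.null(ref)) {
    lapply(setNames(nm = config$sensitive), function(a) {
      tab <- table(output[[a]])
      v <- as.numeric(tab) / n
      names(v) <- names(tab)
      v[sort(names(v), method = "radix")]
    })
  } else {
    ref$dist
  }

  suppressed <- rep(TRUE, n)
  for (a in qis) suppressed <- suppressed & output[[a]] == "*"
  kept <- output[!suppressed, , drop = FALSE]

  groups <- if (nrow(kept) == 0L) list() else {
    key <- apply(as.matrix(kept[qis]), 1L, paste, collapse = "\x1F")
    g <- split(seq_len(nrow(kept)), key)
    g[sort(names(g), method = "radix")]
  }
  sizes <- vapply(groups, length, integer(1))

  eval_model <- function(m) {
    tol <- 1e-9
    sens_counts <- function() {
      lapply(groups, function(ii) table(kept[[m$sensitive]][ii]))
    }
    freq_and_ref <- function(cnt) {
      p <- as.numeric(cnt) / sum(cnt)
      names(p) <- names(cnt)
      q <- refd[[m$sensitive]]
      full <- setNames(numeric(length(q)), names(q))
      full[names(p)] <- p
      list(p = full, q = q)
    }
    if (length(groups) == 0L && m$level == "class") {
      return(list(pass = TRUE, worst = NA_real_))
    }
    switch(m$registry_key,
      k_anonymity = {
        worst <- min(sizes)
        list(pass = worst >= m$params$k, worst = worst)
      },
      distinct_l = {
        d <- vapply(sens_counts(), function(cnt) sum(cnt > 0), integer(1))
        list(pass = min(d) >= m$params$l, worst = min(d))
      },
      entropy_l_shannon = {
        H <- vapply(sens_counts(), function(cnt) {
          p <- as.numeric(cnt[cnt > 0]) / sum(cnt)
          -sum(p * log(p))
        }, numeric(1))
        list(pass = min(H) >= log(m$params$l) - tol, worst = min(H))
      },
      entropy_l_grassberger = {
        H <- vapply(sens_counts(), function(cnt) {
          x <- as.numeric(cnt[cnt > 0])
          nn <- sum(x)
          G <- digamma(x) + ((-1)^x / 2) * (digamma((x + 1) / 2) - digamma(x / 2))
          log(nn) - sum(x * G) / nn
        }, numeric(1))
        list(pass = min(H) >= log(m$params$l) - tol, worst = min(H))
      },
      recursive_cl = {
        ok <- vapply(sens_counts(), function(cnt) {
          r <- sort(as.numeric(cnt[cnt > 0]), decreasing = TRUE)
          if (m$params$l > length(r)) return(FALSE)
          r[[1L]] < m$params$c * sum(r[m$params$l:length(r)])
        }, logical(1))
        list(pass = all(ok), worst = sum(!ok))
      },
      t_closeness_equal = {
        d <- vapply(sens_counts(), function(cnt) {
          pq <- freq_and_ref(cnt)
          sum(abs(pq$p - pq$q)) / 2
        }, numeric(1))
        list(pass = max(d) <= m$params$t + tol, worst = max(d))
      },
      t_closeness_ordered = {
        ord <- m$order
        if (is.null(ord)) ord <- sort(names(refd[[m$sensitive]]), method = "radix")
        d <- vapply(sens_counts(), function(cnt) {
          pq <- freq_and_ref(cnt)
          p <- pq$p[ord]
          q <- pq$q[ord]
          mm <- length(p)
          if (mm < 2L) return(0)
          cum <- cumsum(p - q)
          sum(abs(cum[-mm])) / (mm - 1)
        }, numeric(1))
        list(pass = max(d) <= m$params$t + tol, worst = max(d))
      },
      delta_disclosure = {
        d <- vapply(sens_counts(), function(cnt) {
          pq <- freq_and_ref(cnt)
          pos <- pq$p > 0
          if (any(pos & pq$q == 0)) return(Inf)
          max(abs(log(pq$p[pos] / pq$q[pos]) / log(m$log_base)))
        }, numeric(1))
        list(pass = max(d) < m$params$delta, worst = max(d))
      },
      beta_likeness_basic = ,
      beta_likeness_enhanced = {
        enhanced <- m$registry_key == "beta_likeness_enhanced"
        excess <- vapply(sens_counts(), function(cnt) {
          pq <- freq_and_ref(cnt)
          sel <- pq$q > 0 & pq$p > pq$q
          if (!any(sel)) return(-Inf)
          gain <- (pq$p[sel] - pq$q[sel]) / pq$q[sel]
          bound <- if (enhanced) pmin(m$params$beta, -log(pq$q[sel])) else m$params$beta
          max(gain - bound)
        }, numeric(1))
        list(pass = max(excess) <= tol, worst = max(excess))
      },
      average_risk = {
        risk <- if (sum(sizes) == 0) 0 else length(sizes) / sum(sizes)
        list(pass = risk <= m$params$threshold + tol, worst = risk)
      },
      sample_uniqueness = {
        u <- if (sum(sizes) == 0) 0 else sum(sizes[sizes == 1]) / sum(sizes)
        list(pass = u <= m$params$threshold + tol, worst = u)
      },
      abort_p4(sprintf("unknown model kind '%s'", m$registry_key), "p4_error_model")
    )
  }

  rows <- lapply(config$models, function(m) {
    r <- eval_model(m)
    tibble::tibble(model = model_label(m), level = m$level,
                   monotonic = is_monotonic(m), pass = r$pass,
                   worst = as.numeric(r$worst))
  })
  models_tbl <- if (length(rows) > 0L) dplyr::bind_rows(rows) else {
    tibble::tibble(model = character(0), level = character(0),
                   monotonic = logical(0), pass = logical(0),
                   worst = numeric(0))
  }
  structure(
    list(
      pass = all(models_tbl$pass),
      models = models_tbl,
      n_records = n,
      n_suppressed = sum(suppressed),
      n_classes = length(sizes)
    ),
    class = "privacy_check"
  )
}

#' @export
print.privacy_check <- function(x, ...) {
  cat(sprintf("<privacy_check: %s | %d records (%d suppressed), %d classes>\n",
              if (x$pass) "PASS" else "FAIL",
              x$n_records, x$n_suppressed, x$n_classes))
  print(x$models)
  invisible(x)
}

#' @export
tidy.privacy_check <- function(x, ...) x$models

#' @export
glance.privacy_check <- function(x, ...) {
  tibble::tibble(pass = x$pass, n_records = x$n_records,
                 n_suppressed = x$n_suppressed, n_classes = x$n_classes)
}
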