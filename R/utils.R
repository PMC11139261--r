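# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else suppressWarnings(rm(".Random.seed", envir = genv))
    })
    set.seed(as.integer(seed))
    expr
}

# 32-bit FNV-1a over a canonical character rendering; provenance only.
fnv1aHash <- function(x) {
    bytes <- utf8ToInt(paste(x, collapse = "\x1f")) %% 256
    h <- 2166136261
    p <- 16777619
    for (b in bytes) {
        lo <- h %% 256
        h <- h - lo + bitwXor(lo, b)
        # 32-bit modular multiply in 16-bit halves to stay exact in doubles
        hLo <- h %% 65536; hHi <- h %/% 65536
        h <- (hLo * p + ((hHi * p) %% 65536) * 65536) %% 4294967296
    }
    sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
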