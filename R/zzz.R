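.onLoad <- function(libname, pkgname) {
    # OpenBabel writes its message log straight to the C++ stderr stream,
    # which cannot be captured from R; turn logging off once at load time.
    tryCatch({
        stopLogging <- utils::getFromNamespace(
            "OBMessageHandler_StopLogging", "ChemmineOB")
        errLog <- utils::getFromNamespace("obErrorLog_get", "ChemmineOB")
        stopLogging(errLog())
    }, error = function(e) invisible(NULL))
    invisible(NULL)
}
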