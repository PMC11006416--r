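// glibc malloc tuning: keep large matrix buffers on the heap instead of
// per-allocation mmap/munmap, which dominates runtime for the training
// loop's short-lived multi-megabyte temporaries.
#include <Rcpp.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif

// [[Rcpp::export(name = ".cpp_tune_allocator")]]
void cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_MAX, 0);
  mallopt(M_TRIM_THRESHOLD, -1);
#endif
}
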