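#include <Rcpp.h>
#include "rangecoder.h"

using namespace Rcpp;
using namespace fqcm;

// ---- static multi-symbol interface (test / reference surface) --------------

// [[Rcpp::export]]
RawVector rc_encode_static_(IntegerVector symbols, IntegerVector freqs) {
    int nsym = freqs.size();
    uint32_t tot = 0;
    std::vector<uint32_t> cf(nsym + 1, 0);
    for (int i = 0; i < nsym; ++i) {
        if (freqs[i] < 0) stop("negative frequency");
        cf[i] = tot;
        tot += (uint32_t)freqs[i];
    }
    cf[nsym] = tot;
    if (tot == 0 || tot > 65536) stop("total frequency must be in [1, 65536]");
    RangeEncoder enc;
    for (int i = 0; i < symbols.size(); ++i) {
        int s = symbols[i] - 1;  // R is 1-based
        if (s < 0 || s >= nsym) stop("symbol index out of range at position %d", i + 1);
        if (freqs[s] == 0)
            stop("zero-probability symbol %d at position %d", s + 1, i + 1);
        enc.encode(cf[s], (uint32_t)freqs[s], tot);
    }
    enc.flush();
    return RawVector(enc.out.begin(), enc.out.end());
}

// [[Rcpp::export]]
IntegerVector rc_decode_static_(RawVector payload, IntegerVector freqs, int n) {
    int nsym = freqs.size();
    uint32_t tot = 0;
    std::vector<uint32_t> cf(nsym + 1, 0);
    for (int i = 0; i < nsym; ++i) {
        cf[i] = tot;
        tot += (uint32_t)freqs[i];
    }
    cf[nsym] = tot;
    if (tot == 0 || tot > 65536) stop("total frequency must be in [1, 65536]");
    RangeDecoder dec((const uint8_t*)RAW(payload), payload.size());
    IntegerVector outv(n);
    for (int i = 0; i < n; ++i) {
        uint32_t dv = dec.decode_target(tot);
        int s = 0;
        while ((uint32_t)dv >= cf[s + 1]) ++s;
        dec.decode_update(cf[s], (uint32_t)freqs[s]);
        outv[i] = s + 1;
    }
    if (!dec.clean(payload.size()))
        stop("corrupt or truncated payload (consumed %d of %d bytes)",
             (int)dec.consumed(), (int)payload.size());
    return outv;
}

// ---- static binary interface -----------------------------------------------

// [[Rcpp::export]]
RawVector rc_encode_bits_(IntegerVector bits, int p1) {
    if (p1 < 1 || p1 > 65535) stop("p1 must be in [1, 65535]");
    RangeEncoder enc;
    for (int i = 0; i < bits.size(); ++i) enc.encode_bit(bits[i] != 0, (uint32_t)p1);
    enc.flush();
    return RawVector(enc.out.begin(), enc.out.end());
}

// [[Rcpp::export]]
IntegerVector rc_decode_bits_(RawVector payload, int p1, int n) {
    if (p1 < 1 || p1 > 65535) stop("p1 must be in [1, 65535]");
    RangeDecoder dec((const uint8_t*)RAW(payload), payload.size());
    IntegerVector outv(n);
    for (int i = 0; i < n; ++i) outv[i] = dec.decode_bit((uint32_t)p1);
    if (!dec.clean(payload.size()))
        stop("corrupt or truncated payload (consumed %d of %d bytes)",
             (int)dec.consumed(), (int)payload.size());
    return outv;
}

// ---- adaptive order-0 symbol coder (round-trip reference) ------------------

namespace {
struct Order0Model {
    std::vector<uint32_t> counts;
    uint32_t total;
    explicit Order0Model(int nsym) : counts(nsym, 1), total(nsym) {}
    void freqs(std::vector<uint32_t>& f, uint32_t& tot) const {
        f = counts;
        tot = total;
    }
    void update(int s) {
        counts[s] += 32;
        total += 32;
        if (total >= 60000) {
            total = 0;
            for (auto& c : counts) {
                c = (c >> 1) | 1;
                total += c;
            }
        }
    }
};
}

// [[Rcpp::export]]
RawVector rc_encode_adaptive_(IntegerVector symbols, int nsym) {
    Order0Model m(nsym);
    RangeEncoder enc;
    std::vector<uint32_t> f;
    uint32_t tot;
    for (int i = 0; i < symbols.size(); ++i) {
        int s = symbols[i] - 1;
        if (s < 0 || s >= nsym) stop("symbol index out of range at position %d", i + 1);
        m.freqs(f, tot);
        uint32_t cf = 0;
        for (int j = 0; j < s; ++j) cf += f[j];
        enc.encode(cf, f[s], tot);
        m.update(s);
    }
    enc.flush();
    return RawVector(enc.out.begin(), enc.out.end());
}

// [[Rcpp::export]]
IntegerVector rc_decode_adaptive_(RawVector payload, int nsym, int n) {
    Order0Model m(nsym);
    RangeDecoder dec((const uint8_t*)RAW(payload), payload.size());
    IntegerVector outv(n);
    std::vector<uint32_t> f;
    uint32_t tot;
    for (int i = 0; i < n; ++i) {
        m.freqs(f, tot);
        uint32_t dv = dec.decode_target(tot);
        uint32_t cf = 0;
        int s = 0;
        while (cf + f[s] <= dv) { cf += f[s]; ++s; }
        dec.decode_update(cf, f[s]);
        m.update(s);
        outv[i] = s + 1;
    }
    if (!dec.clean(payload.size()))
        stop("corrupt or truncated payload (consumed %d of %d bytes)",
             (int)dec.consumed(), (int)payload.size());
    return outv;
}

// ---- adaptive order-k byte stream FCM (identifier / length payloads) -------

namespace {
// order-k finite-context model over bytes, alpha = 1 via "+1" in frequencies;
// counts are stored scaled by 16 so halving keeps resolution.
struct ByteFCM {
    int order;
    uint32_t mask;
    std::vector<uint16_t> counts;  // ctx * 256 + byte
    std::vector<uint32_t> totals;

    explicit ByteFCM(int k) : order(k) {
        size_t nctx = 1;
        for (int i = 0; i < k; ++i) nctx *= 256;
        mask = (uint32_t)(nctx - 1);
        counts.assign(nctx * 256, 0);
        totals.assign(nctx, 0);
    }

    // frequency of byte b in ctx is counts+1; total is totals + 256
    void code_freq(uint32_t ctx, int b, uint32_t& cf, uint32_t& f, uint32_t& tot) const {
        const uint16_t* row = &counts[(size_t)ctx * 256];
        uint32_t c = 0;
        for (int j = 0; j < b; ++j) c += row[j];
        cf = c + (uint32_t)b;
        f = row[b] + 1u;
        tot = totals[ctx] + 256u;
    }

    int find(uint32_t ctx, uint32_t dv, uint32_t& cf, uint32_t& f) const {
        const uint16_t* row = &counts[(size_t)ctx * 256];
        uint32_t c = 0;
        int b = 0;
        for (;;) {
            uint32_t fb = row[b] + 1u;
            if (c + fb > dv) { cf = c; f = fb; return b; }
            c += fb;
            ++b;
        }
    }

    void update(uint32_t ctx, int b) {
        uint16_t* row = &counts[(size_t)ctx * 256];
        row[b] += 24;
        totals[ctx] += 24;
        if (totals[ctx] + 256u > 60000u) {
            uint32_t t = 0;
            for (int j = 0; j < 256; ++j) {
                row[j] >>= 1;
                t += row[j];
            }
            totals[ctx] = t;
        }
    }
};
}

// [[Rcpp::export]]
RawVector fcm_bytes_encode_(RawVector data, int order) {
    if (order < 0 || order > 2) stop("byte FCM order must be 0, 1 or 2");
    ByteFCM m(order);
    RangeEncoder enc;
    uint32_t ctx = 0;
    const uint8_t* p = (const uint8_t*)RAW(data);
    for (R_xlen_t i = 0; i < data.size(); ++i) {
        int b = p[i];
        uint32_t cf, f, tot;
        m.code_freq(ctx, b, cf, f, tot);
        enc.encode(cf, f, tot);
        m.update(ctx, b);
        ctx = ((ctx << 8) | (uint32_t)b) & m.mask;
    }
    enc.flush();
    return RawVector(enc.out.begin(), enc.out.end());
}

// [[Rcpp::export]]
RawVector fcm_bytes_decode_(RawVector payload, double n, int order) {
    if (order < 0 || order > 2) stop("byte FCM order must be 0, 1 or 2");
    ByteFCM m(order);
    RangeDecoder dec((const uint8_t*)RAW(payload), payload.size());
    R_xlen_t len = (R_xlen_t)n;
    RawVector outv(len);
    uint32_t ctx = 0;
    for (R_xlen_t i = 0; i < len; ++i) {
        uint32_t tot = m.totals[ctx] + 256u;
        uint32_t dv = dec.decode_target(tot);
        uint32_t cf, f;
        int b = m.find(ctx, dv, cf, f);
        dec.decode_update(cf, f);
        m.update(ctx, b);
        outv[i] = (Rbyte)b;
        ctx = ((ctx << 8) | (uint32_t)b) & m.mask;
    }
    if (!dec.clean(payload.size()))
        stop("corrupt or truncated payload (consumed %d of %d bytes)",
             (int)dec.consumed(), (int)payload.size());
    return outv;
}

// ---- checksums --------------------------------------------------------------

// [[Rcpp::export]]
RawVector fnv1a64_(RawVector data) {
    uint64_t h = fnv1a64((const uint8_t*)RAW(data), data.size());
    RawVector outv(8);
    for (int i = 0; i < 8; ++i) outv[i] = (Rbyte)((h >> (8 * i)) & 0xFF);  // little-endian
    return outv;
}
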