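#include <Rcpp.h>
using namespace Rcpp;

// Online Kohonen update loop.  X: n x d data, proto: U x d prototypes
// (modified copy returned), ord: 1-based row indices presented in order,
// lr / radius: per-step schedules, gridpos: U x 2 unit grid coordinates.
// The best-matching unit is the one with the smallest squared Euclidean
// distance; ties keep the lowest unit index.  Neighborhood is Gaussian in
// grid space, h = exp(-dist2 / (2 sigma^2)).
// [[Rcpp::export]]
NumericMatrix som_train_cpp(NumericMatrix X, NumericMatrix proto_in,
                            IntegerVector ord, NumericVector lr,
                            NumericVector radius, NumericMatrix gridpos) {
    NumericMatrix proto = clone(proto_in);
    const int d = X.ncol();
    const int U = proto.nrow();
    const int steps = ord.size();
    if (lr.size() != steps || radius.size() != steps)
        stop("schedule length must match the number of presentation steps");

    for (int s = 0; s < steps; ++s) {
        const int i = ord[s] - 1;
        // best-matching unit
        int bmu = 0;
        double best = R_PosInf;
        for (int u = 0; u < U; ++u) {
            double d2 = 0.0;
            for (int k = 0; k < d; ++k) {
                const double diff = X(i, k) - proto(u, k);
                d2 += diff * diff;
            }
            if (d2 < best) {   // strict: first minimum wins
                best = d2;
                bmu = u;
            }
        }
        const double sigma2 = 2.0 * radius[s] * radius[s];
        const double a = lr[s];
        const double br = gridpos(bmu, 0), bc = gridpos(bmu, 1);
        for (int u = 0; u < U; ++u) {
            const double dr = gridpos(u, 0) - br;
            const double dc = gridpos(u, 1) - bc;
            const double h = std::exp(-(dr * dr + dc * dc) / sigma2);
            if (h < 1e-8)
                continue;
            const double ah = a * h;
            for (int k = 0; k < d; ++k)
                proto(u, k) += ah * (X(i, k) - proto(u, k));
        }
    }
    return proto;
}
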