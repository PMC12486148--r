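// Sequence-regression network core: forward passes and exact backprop
// gradients for the five architectures (lstm, bilstm, gru, rnn, transformer).
// Sequences arrive as 0-based letter-index matrices (n x L); the one-hot
// encoding is materialized here. All state is passed in explicitly; the only
// entry points are batch loss/gradient (training) and batch prediction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;
using arma::uvec;

typedef std::map<std::string, mat> ParamMap;

struct Model {
    std::string arch;
    int nlayers;
    int hidden;
    ParamMap P;
};

static Model model_from_list(const std::string& arch, List params,
                             int nlayers, int hidden) {
    Model m;
    m.arch = arch;
    m.nlayers = nlayers;
    m.hidden = hidden;
    CharacterVector nm = params.names();
    for (int i = 0; i < params.size(); ++i) {
        std::string key = as<std::string>(nm[i]);
        NumericVector v(params[i]);
        if (Rf_isMatrix(params[i])) {
            m.P[key] = as<mat>(params[i]);
        } else {
            // plain vectors (biases, readout) become 1 x k row matrices
            m.P[key] = mat(as<rowvec>(v));
        }
    }
    return m;
}

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + arma::exp(-z)); }

static std::vector<mat> one_hot_steps(const IntegerMatrix& X) {
    int n = X.nrow(), L = X.ncol();
    std::vector<mat> xs(L);
    for (int t = 0; t < L; ++t) {
        mat x(n, 20, arma::fill::zeros);
        for (int b = 0; b < n; ++b) x(b, X(b, t)) = 1.0;
        xs[t] = x;
    }
    return xs;
}

// ---------------- LSTM (one direction) ----------------

struct LstmCache {
    std::vector<mat> hprev, cprev, gi, gf, gg, go, tc;
    std::vector<mat> hs; // outputs per step
};

static void lstm_forward(const std::vector<mat>& xs, const mat& Wx,
                         const mat& Wh, const rowvec& b, int H,
                         LstmCache& cc) {
    int L = xs.size();
    int B = xs[0].n_rows;
    mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
    cc.hprev.resize(L); cc.cprev.resize(L); cc.gi.resize(L); cc.gf.resize(L);
    cc.gg.resize(L); cc.go.resize(L); cc.tc.resize(L); cc.hs.resize(L);
    for (int t = 0; t < L; ++t) {
        cc.hprev[t] = h; cc.cprev[t] = c;
        mat Z = xs[t] * Wx + h * Wh;
        Z.each_row() += b;
        mat gi = sigm(Z.cols(0, H - 1));
        mat gf = sigm(Z.cols(H, 2 * H - 1));
        mat gg = arma::tanh(Z.cols(2 * H, 3 * H - 1));
        mat go = sigm(Z.cols(3 * H, 4 * H - 1));
        c = gf % c + gi % gg;
        mat tc = arma::tanh(c);
        h = go % tc;
        cc.gi[t] = gi; cc.gf[t] = gf; cc.gg[t] = gg; cc.go[t] = go;
        cc.tc[t] = tc; cc.hs[t] = h;
    }
}

// dhs: per-step output gradients (may be empty mats); returns dxs, fills grads
static std::vector<mat> lstm_backward(const std::vector<mat>& xs,
                                      const std::vector<mat>& dhs,
                                      const mat& Wx, const mat& Wh, int H,
                                      const LstmCache& cc, mat& dWx, mat& dWh,
                                      rowvec& db, bool need_dx) {
    int L = xs.size();
    int B = xs[0].n_rows;
    dWx.zeros(Wx.n_rows, Wx.n_cols);
    dWh.zeros(Wh.n_rows, Wh.n_cols);
    db.zeros(4 * H);
    std::vector<mat> dxs(need_dx ? L : 0);
    mat dh_next(B, H, arma::fill::zeros), dc_next(B, H, arma::fill::zeros);
    for (int t = L - 1; t >= 0; --t) {
        mat dh = dh_next;
        if (dhs[t].n_elem > 0) dh += dhs[t];
        const mat& gi = cc.gi[t]; const mat& gf = cc.gf[t];
        const mat& gg = cc.gg[t]; const mat& go = cc.go[t];
        const mat& tc = cc.tc[t];
        mat dgo = dh % tc;
        mat dc = dc_next + dh % go % (1.0 - tc % tc);
        mat dgi = dc % gg;
        mat dgf = dc % cc.cprev[t];
        mat dgg = dc % gi;
        dc_next = dc % gf;
        mat dZ(B, 4 * H);
        dZ.cols(0, H - 1) = dgi % gi % (1.0 - gi);
        dZ.cols(H, 2 * H - 1) = dgf % gf % (1.0 - gf);
        dZ.cols(2 * H, 3 * H - 1) = dgg % (1.0 - gg % gg);
        dZ.cols(3 * H, 4 * H - 1) = dgo % go % (1.0 - go);
        dWx += xs[t].t() * dZ;
        dWh += cc.hprev[t].t() * dZ;
        db += arma::sum(dZ, 0);
        dh_next = dZ * Wh.t();
        if (need_dx) dxs[t] = dZ * Wx.t();
    }
    return dxs;
}

// ---------------- GRU ----------------

struct GruCache {
    std::vector<mat> hprev, gz, gr, gn, rh;
    std::vector<mat> hs;
};

static void gru_forward(const std::vector<mat>& xs, const mat& Wx,
                        const mat& Whzr, const mat& Whn, const rowvec& b,
                        int H, GruCache& cc) {
    int L = xs.size();
    int B = xs[0].n_rows;
    mat h(B, H, arma::fill::zeros);
    cc.hprev.resize(L); cc.gz.resize(L); cc.gr.resize(L); cc.gn.resize(L);
    cc.rh.resize(L); cc.hs.resize(L);
    for (int t = 0; t < L; ++t) {
        cc.hprev[t] = h;
        mat A = xs[t] * Wx;   // B x 3H: [z r n] input parts
        A.each_row() += b;
        mat Azr = A.cols(0, 2 * H - 1) + h * Whzr;
        mat gz = sigm(Azr.cols(0, H - 1));
        mat gr = sigm(Azr.cols(H, 2 * H - 1));
        mat rh = gr % h;
        mat gn = arma::tanh(A.cols(2 * H, 3 * H - 1) + rh * Whn);
        h = (1.0 - gz) % gn + gz % h;
        cc.gz[t] = gz; cc.gr[t] = gr; cc.gn[t] = gn; cc.rh[t] = rh;
        cc.hs[t] = h;
    }
}

static std::vector<mat> gru_backward(const std::vector<mat>& xs,
                                     const std::vector<mat>& dhs,
                                     const mat& Wx, const mat& Whzr,
                                     const mat& Whn, int H,
                                     const GruCache& cc, mat& dWx, mat& dWhzr,
                                     mat& dWhn, rowvec& db, bool need_dx) {
    int L = xs.size();
    int B = xs[0].n_rows;
    dWx.zeros(Wx.n_rows, Wx.n_cols);
    dWhzr.zeros(Whzr.n_rows, Whzr.n_cols);
    dWhn.zeros(Whn.n_rows, Whn.n_cols);
    db.zeros(3 * H);
    std::vector<mat> dxs(need_dx ? L : 0);
    mat dh_next(B, H, arma::fill::zeros);
    for (int t = L - 1; t >= 0; --t) {
        mat dh = dh_next;
        if (dhs[t].n_elem > 0) dh += dhs[t];
        const mat& gz = cc.gz[t]; const mat& gr = cc.gr[t];
        const mat& gn = cc.gn[t]; const mat& hprev = cc.hprev[t];
        mat dgz = dh % (hprev - gn);
        mat dgn = dh % (1.0 - gz);
        mat dh_prev = dh % gz;
        mat dAn = dgn % (1.0 - gn % gn);
        mat drh = dAn * Whn.t();
        mat dgr = drh % hprev;
        dh_prev += drh % gr;
        mat dAz = dgz % gz % (1.0 - gz);
        mat dAr = dgr % gr % (1.0 - gr);
        mat dAzr(B, 2 * H);
        dAzr.cols(0, H - 1) = dAz;
        dAzr.cols(H, 2 * H - 1) = dAr;
        dh_prev += dAzr * Whzr.t();
        dWhzr += hprev.t() * dAzr;
        dWhn += cc.rh[t].t() * dAn;
        mat dA(B, 3 * H);
        dA.cols(0, 2 * H - 1) = dAzr;
        dA.cols(2 * H, 3 * H - 1) = dAn;
        dWx += xs[t].t() * dA;
        db += arma::sum(dA, 0);
        if (need_dx) dxs[t] = dA * Wx.t();
        dh_next = dh_prev;
    }
    return dxs;
}

// ---------------- vanilla RNN ----------------

struct RnnCache {
    std::vector<mat> hprev, hs;
};

static void rnn_forward(const std::vector<mat>& xs, const mat& Wx,
                        const mat& Wh, const rowvec& b, int H, RnnCache& cc) {
    int L = xs.size();
    int B = xs[0].n_rows;
    mat h(B, H, arma::fill::zeros);
    cc.hprev.resize(L); cc.hs.resize(L);
    for (int t = 0; t < L; ++t) {
        cc.hprev[t] = h;
        mat Z = xs[t] * Wx + h * Wh;
        Z.each_row() += b;
        h = arma::tanh(Z);
        cc.hs[t] = h;
    }
}

static std::vector<mat> rnn_backward(const std::vector<mat>& xs,
                                     const std::vector<mat>& dhs,
                                     const mat& Wx, const mat& Wh, int H,
                                     const RnnCache& cc, mat& dWx, mat& dWh,
                                     rowvec& db, bool need_dx) {
    int L = xs.size();
    int B = xs[0].n_rows;
    dWx.zeros(Wx.n_rows, Wx.n_cols);
    dWh.zeros(Wh.n_rows, Wh.n_cols);
    db.zeros(H);
    std::vector<mat> dxs(need_dx ? L : 0);
    mat dh_next(B, H, arma::fill::zeros);
    for (int t = L - 1; t >= 0; --t) {
        mat dh = dh_next;
        if (dhs[t].n_elem > 0) dh += dhs[t];
        mat dZ = dh % (1.0 - cc.hs[t] % cc.hs[t]);
        dWx += xs[t].t() * dZ;
        dWh += cc.hprev[t].t() * dZ;
        db += arma::sum(dZ, 0);
        dh_next = dZ * Wh.t();
        if (need_dx) dxs[t] = dZ * Wx.t();
    }
    return dxs;
}

// ---------------- shared recurrent stack ----------------

static std::string key(const char* base, int layer) {
    char buf[32];
    std::snprintf(buf, sizeof(buf), "%s_%d", base, layer + 1);
    return std::string(buf);
}

// Runs the recurrent stack forward; returns per-layer per-step inputs and
// caches so the backward pass can be replayed. `readout` receives the final
// feature matrix (B x H, or B x 2H for bilstm).
struct RecState {
    std::vector< std::vector<mat> > inputs; // inputs[l] = xs fed to layer l
    std::vector<LstmCache> lstm_f, lstm_b;
    std::vector<GruCache> gru;
    std::vector<RnnCache> rnn;
};

static mat rec_forward(const Model& m, const std::vector<mat>& xs0,
                       RecState& st) {
    int H = m.hidden;
    int L = xs0.size();
    std::vector<mat> xs = xs0;
    st.inputs.resize(m.nlayers);
    if (m.arch == "lstm") st.lstm_f.resize(m.nlayers);
    if (m.arch == "bilstm") { st.lstm_f.resize(m.nlayers); st.lstm_b.resize(m.nlayers); }
    if (m.arch == "gru") st.gru.resize(m.nlayers);
    if (m.arch == "rnn") st.rnn.resize(m.nlayers);
    for (int l = 0; l < m.nlayers; ++l) {
        st.inputs[l] = xs;
        if (m.arch == "lstm") {
            lstm_forward(xs, m.P.at(key("Wx", l)), m.P.at(key("Wh", l)),
                         m.P.at(key("b", l)).row(0), H, st.lstm_f[l]);
            xs = st.lstm_f[l].hs;
        } else if (m.arch == "gru") {
            gru_forward(xs, m.P.at(key("Wx", l)), m.P.at(key("Whzr", l)),
                        m.P.at(key("Whn", l)), m.P.at(key("b", l)).row(0), H,
                        st.gru[l]);
            xs = st.gru[l].hs;
        } else if (m.arch == "rnn") {
            rnn_forward(xs, m.P.at(key("Wx", l)), m.P.at(key("Wh", l)),
                        m.P.at(key("b", l)).row(0), H, st.rnn[l]);
            xs = st.rnn[l].hs;
        } else { // bilstm
            std::vector<mat> rev(L);
            for (int t = 0; t < L; ++t) rev[t] = xs[L - 1 - t];
            lstm_forward(xs, m.P.at(key("Wxf", l)), m.P.at(key("Whf", l)),
                         m.P.at(key("bf", l)).row(0), H, st.lstm_f[l]);
            lstm_forward(rev, m.P.at(key("Wxb", l)), m.P.at(key("Whb", l)),
                         m.P.at(key("bb", l)).row(0), H, st.lstm_b[l]);
            std::vector<mat> out(L);
            for (int t = 0; t < L; ++t)
                out[t] = arma::join_rows(st.lstm_f[l].hs[t],
                                         st.lstm_b[l].hs[L - 1 - t]);
            xs = out;
        }
    }
    if (m.arch == "bilstm") {
        // final features: forward state at last step, backward state at its
        // own last step (original position 1)
        int last = L - 1;
        return arma::join_rows(st.lstm_f[m.nlayers - 1].hs[last],
                               st.lstm_b[m.nlayers - 1].hs[last]);
    }
    return xs[L - 1];
}

// dfeat: gradient at the readout features; accumulates parameter grads
static void rec_backward(const Model& m, const mat& dfeat, RecState& st,
                         ParamMap& G) {
    int H = m.hidden;
    int L = st.inputs[0].size();
    int B = dfeat.n_rows;
    // per-step output gradient entering the top layer
    std::vector<mat> dhs(L);
    if (m.arch == "bilstm") {
        for (int t = 0; t < L; ++t) dhs[t] = mat();
    } else {
        for (int t = 0; t < L; ++t) dhs[t] = mat();
        dhs[L - 1] = dfeat;
    }
    // bilstm: inject readout grads at the two final states directly below
    for (int l = m.nlayers - 1; l >= 0; --l) {
        bool need_dx = l > 0;
        std::vector<mat> dxs;
        if (m.arch == "lstm") {
            mat dWx, dWh; rowvec db;
            dxs = lstm_backward(st.inputs[l], dhs, m.P.at(key("Wx", l)),
                                m.P.at(key("Wh", l)), H, st.lstm_f[l],
                                dWx, dWh, db, need_dx);
            G[key("Wx", l)] = dWx; G[key("Wh", l)] = dWh; G[key("b", l)] = mat(db);
        } else if (m.arch == "gru") {
            mat dWx, dWhzr, dWhn; rowvec db;
            dxs = gru_backward(st.inputs[l], dhs, m.P.at(key("Wx", l)),
                               m.P.at(key("Whzr", l)), m.P.at(key("Whn", l)),
                               H, st.gru[l], dWx, dWhzr, dWhn, db, need_dx);
            G[key("Wx", l)] = dWx; G[key("Whzr", l)] = dWhzr;
            G[key("Whn", l)] = dWhn; G[key("b", l)] = mat(db);
        } else if (m.arch == "rnn") {
            mat dWx, dWh; rowvec db;
            dxs = rnn_backward(st.inputs[l], dhs, m.P.at(key("Wx", l)),
                               m.P.at(key("Wh", l)), H, st.rnn[l],
                               dWx, dWh, db, need_dx);
            G[key("Wx", l)] = dWx; G[key("Wh", l)] = dWh; G[key("b", l)] = mat(db);
        } else { // bilstm
            // split per-step grads into forward/backward halves
            std::vector<mat> dhf(L), dhb_rev(L);
            for (int t = 0; t < L; ++t) { dhf[t] = mat(); dhb_rev[t] = mat(); }
            for (int t = 0; t < L; ++t) {
                if (dhs[t].n_elem > 0) {
                    dhf[t] = dhs[t].cols(0, H - 1);
                    // backward cell processed original step t at reversed
                    // index L-1-t
                    mat g = dhs[t].cols(H, 2 * H - 1);
                    if (dhb_rev[L - 1 - t].n_elem > 0) dhb_rev[L - 1 - t] += g;
                    else dhb_rev[L - 1 - t] = g;
                }
            }
            if (l == m.nlayers - 1) {
                // readout features: [hf at last step, hb at its last step]
                mat df = dfeat.cols(0, H - 1);
                mat dbk = dfeat.cols(H, 2 * H - 1);
                if (dhf[L - 1].n_elem > 0) dhf[L - 1] += df; else dhf[L - 1] = df;
                if (dhb_rev[L - 1].n_elem > 0) dhb_rev[L - 1] += dbk;
                else dhb_rev[L - 1] = dbk;
            }
            std::vector<mat> rev(L);
            for (int t = 0; t < L; ++t) rev[t] = st.inputs[l][L - 1 - t];
            mat dWxf, dWhf, dWxb, dWhb; rowvec dbf, dbb;
            std::vector<mat> dxf = lstm_backward(st.inputs[l], dhf,
                m.P.at(key("Wxf", l)), m.P.at(key("Whf", l)), H,
                st.lstm_f[l], dWxf, dWhf, dbf, need_dx);
            std::vector<mat> dxb = lstm_backward(rev, dhb_rev,
                m.P.at(key("Wxb", l)), m.P.at(key("Whb", l)), H,
                st.lstm_b[l], dWxb, dWhb, dbb, need_dx);
            G[key("Wxf", l)] = dWxf; G[key("Whf", l)] = dWhf; G[key("bf", l)] = mat(dbf);
            G[key("Wxb", l)] = dWxb; G[key("Whb", l)] = dWhb; G[key("bb", l)] = mat(dbb);
            if (need_dx) {
                dxs.resize(L);
                for (int t = 0; t < L; ++t) dxs[t] = dxf[t] + dxb[L - 1 - t];
            }
        }
        if (need_dx) {
            dhs = dxs;
            if (m.arch == "bilstm") {
                // lower bilstm layers receive full per-step gradients
            } else if (l > 0) {
                // recurrent stacks propagate per-step grads as-is
            }
        }
    }
    (void)B;
}

// ---------------- transformer ----------------

// activations stored as (B*L) x H with row index t*B + b

struct LnCache { mat xhat; vec inv_sd; };

static mat layernorm_forward(const mat& X, const rowvec& g, const rowvec& b,
                             LnCache& cc) {
    vec mu = arma::mean(X, 1);
    mat C = X;
    C.each_col() -= mu;
    vec v = arma::mean(arma::square(C), 1);
    cc.inv_sd = 1.0 / arma::sqrt(v + 1e-5);
    C.each_col() %= cc.inv_sd;
    cc.xhat = C;
    mat Y = cc.xhat;
    Y.each_row() %= g;
    Y.each_row() += b;
    return Y;
}

static mat layernorm_backward(const mat& dY, const rowvec& g,
                              const LnCache& cc, rowvec& dg, rowvec& dbta) {
    dg = arma::sum(dY % cc.xhat, 0);
    dbta = arma::sum(dY, 0);
    mat dxhat = dY;
    dxhat.each_row() %= g;
    vec m1 = arma::mean(dxhat, 1);
    vec m2 = arma::mean(dxhat % cc.xhat, 1);
    mat dX = dxhat;
    dX.each_col() -= m1;
    mat t2 = cc.xhat;
    t2.each_col() %= m2;
    dX -= t2;
    dX.each_col() %= cc.inv_sd;
    return dX;
}

struct TfLayerCache {
    LnCache ln1, ln2;
    mat Xin, N1, Q, K, V, Attn, Aout, Xmid, N2, Hff;
    arma::cube A; // L x L x B attention weights
};

struct TfCache {
    std::vector<TfLayerCache> layers;
    LnCache lnf;
    mat emb, Nf, pooled;
    int B, L;
};

static mat pos_encoding(int L, int H) {
    mat P(L, H);
    for (int t = 0; t < L; ++t)
        for (int k = 0; k < H; ++k) {
            double angle = t / std::pow(10000.0, (2.0 * (k / 2)) / H);
            P(t, k) = (k % 2 == 0) ? std::sin(angle) : std::cos(angle);
        }
    return P;
}

static uvec item_rows(int b, int B, int L) {
    uvec r(L);
    for (int t = 0; t < L; ++t) r[t] = (arma::uword)(t * B + b);
    return r;
}

static mat tf_forward(const Model& m, const IntegerMatrix& X, TfCache& cc) {
    int B = X.nrow(), L = X.ncol(), H = m.hidden;
    cc.B = B; cc.L = L;
    const mat& We = m.P.at("We");
    mat pe = pos_encoding(L, H);
    mat A0(B * L, H);
    for (int t = 0; t < L; ++t)
        for (int b = 0; b < B; ++b)
            A0.row(t * B + b) = We.row(X(b, t)) + pe.row(t);
    cc.emb = A0;
    cc.layers.resize(m.nlayers);
    double scale = 1.0 / std::sqrt((double)H);
    mat Xc = A0;
    for (int l = 0; l < m.nlayers; ++l) {
        TfLayerCache& lc = cc.layers[l];
        lc.Xin = Xc;
        // pre-norm attention block
        lc.N1 = layernorm_forward(Xc, m.P.at(key("ln1g", l)).row(0),
                                  m.P.at(key("ln1b", l)).row(0), lc.ln1);
        lc.Q = lc.N1 * m.P.at(key("Wq", l));
        lc.K = lc.N1 * m.P.at(key("Wk", l));
        lc.V = lc.N1 * m.P.at(key("Wv", l));
        lc.A.set_size(L, L, B);
        mat O(B * L, H);
        for (int b = 0; b < B; ++b) {
            uvec r = item_rows(b, B, L);
            mat Qb = lc.Q.rows(r), Kb = lc.K.rows(r), Vb = lc.V.rows(r);
            mat S = Qb * Kb.t() * scale;
            S.each_col() -= arma::max(S, 1);
            mat E = arma::exp(S);
            E.each_col() /= arma::sum(E, 1);
            mat Ab = E;
            lc.A.slice(b) = Ab;
            mat Ob = Ab * Vb;
            O.rows(r) = Ob;
        }
        lc.Attn = O;
        lc.Aout = O * m.P.at(key("Wo", l));
        lc.Xmid = Xc + lc.Aout;
        // pre-norm feed-forward block
        lc.N2 = layernorm_forward(lc.Xmid, m.P.at(key("ln2g", l)).row(0),
                                  m.P.at(key("ln2b", l)).row(0), lc.ln2);
        mat Hff = lc.N2 * m.P.at(key("W1", l));
        Hff.each_row() += m.P.at(key("b1", l)).row(0);
        Hff = arma::clamp(Hff, 0.0, arma::datum::inf); // relu
        lc.Hff = Hff;
        mat F2 = Hff * m.P.at(key("W2", l));
        F2.each_row() += m.P.at(key("b2", l)).row(0);
        Xc = lc.Xmid + F2;
    }
    cc.Nf = layernorm_forward(Xc, m.P.at("lnfg").row(0), m.P.at("lnfb").row(0),
                              cc.lnf);
    // mean-pool over positions
    mat pooled(B, H, arma::fill::zeros);
    for (int t = 0; t < L; ++t) pooled += cc.Nf.rows(t * B, t * B + B - 1);
    pooled /= (double)L;
    cc.pooled = pooled;
    return pooled;
}

static void tf_backward(const Model& m, const IntegerMatrix& X,
                        const mat& dpooled, TfCache& cc, ParamMap& G) {
    int B = cc.B, L = cc.L, H = m.hidden;
    double scale = 1.0 / std::sqrt((double)H);
    mat dNf(B * L, H);
    for (int t = 0; t < L; ++t)
        dNf.rows(t * B, t * B + B - 1) = dpooled / (double)L;
    rowvec dg, db;
    mat dX = layernorm_backward(dNf, m.P.at("lnfg").row(0), cc.lnf, dg, db);
    G["lnfg"] = mat(dg); G["lnfb"] = mat(db);
    for (int l = m.nlayers - 1; l >= 0; --l) {
        TfLayerCache& lc = cc.layers[l];
        // feed-forward block
        mat dF2 = dX;                 // gradient of the FF output added to Xmid
        mat dXmid = dX;               // residual path
        G[key("W2", l)] = lc.Hff.t() * dF2;
        G[key("b2", l)] = mat(rowvec(arma::sum(dF2, 0)));
        mat dHff = dF2 * m.P.at(key("W2", l)).t();
        dHff.elem(arma::find(lc.Hff == 0.0)).zeros(); // relu mask
        G[key("W1", l)] = lc.N2.t() * dHff;
        G[key("b1", l)] = mat(rowvec(arma::sum(dHff, 0)));
        mat dN2 = dHff * m.P.at(key("W1", l)).t();
        rowvec dg2, db2;
        dXmid += layernorm_backward(dN2, m.P.at(key("ln2g", l)).row(0),
                                    lc.ln2, dg2, db2);
        G[key("ln2g", l)] = mat(dg2); G[key("ln2b", l)] = mat(db2);
        // attention block
        mat dAout = dXmid;
        mat dXin = dXmid; // residual path
        G[key("Wo", l)] = lc.Attn.t() * dAout;
        mat dO = dAout * m.P.at(key("Wo", l)).t();
        mat dQ(B * L, H, arma::fill::zeros), dK(B * L, H, arma::fill::zeros),
            dV(B * L, H, arma::fill::zeros);
        for (int b = 0; b < B; ++b) {
            uvec r = item_rows(b, B, L);
            mat dOb = dO.rows(r);
            mat Qb = lc.Q.rows(r), Kb = lc.K.rows(r), Vb = lc.V.rows(r);
            mat Ab = lc.A.slice(b);
            mat dAb = dOb * Vb.t();
            dV.rows(r) = Ab.t() * dOb;
            vec rs = arma::sum(dAb % Ab, 1);
            dAb.each_col() -= rs;
            mat dS = Ab % dAb;
            dS *= scale;
            dQ.rows(r) = dS * Kb;
            dK.rows(r) = dS.t() * Qb;
        }
        G[key("Wq", l)] = lc.N1.t() * dQ;
        G[key("Wk", l)] = lc.N1.t() * dK;
        G[key("Wv", l)] = lc.N1.t() * dV;
        mat dN1 = dQ * m.P.at(key("Wq", l)).t() + dK * m.P.at(key("Wk", l)).t()
                + dV * m.P.at(key("Wv", l)).t();
        rowvec dg1, db1;
        dXin += layernorm_backward(dN1, m.P.at(key("ln1g", l)).row(0),
                                   lc.ln1, dg1, db1);
        G[key("ln1g", l)] = mat(dg1); G[key("ln1b", l)] = mat(db1);
        dX = dXin;
    }
    mat dWe(20, H, arma::fill::zeros);
    for (int t = 0; t < L; ++t)
        for (int b = 0; b < B; ++b)
            dWe.row(X(b, t)) += dX.row(t * B + b);
    G["We"] = dWe;
}

// ---------------- readout + entry points ----------------

static vec model_forward(const Model& m, const IntegerMatrix& X,
                         RecState& rst, TfCache& tcc, mat& feat) {
    if (m.arch == "transformer") {
        feat = tf_forward(m, X, tcc);
    } else {
        std::vector<mat> xs = one_hot_steps(X);
        feat = rec_forward(m, xs, rst);
    }
    const mat& w = m.P.at("w_out"); // 1 x F row
    double b0 = m.P.at("b_out")(0, 0);
    vec pred = feat * w.row(0).t() + b0;
    return pred;
}

// [[Rcpp::export(name = ".nn_predict")]]
NumericVector nn_predict_cpp(std::string arch, List params, IntegerMatrix X,
                             int nlayers, int hidden) {
    Model m = model_from_list(arch, params, nlayers, hidden);
    RecState rst; TfCache tcc; mat feat;
    vec pred = model_forward(m, X, rst, tcc, feat);
    return wrap(pred);
}

// [[Rcpp::export(name = ".nn_loss_grad")]]
List nn_loss_grad_cpp(std::string arch, List params, IntegerMatrix X,
                      NumericVector y, int nlayers, int hidden) {
    Model m = model_from_list(arch, params, nlayers, hidden);
    RecState rst; TfCache tcc; mat feat;
    vec pred = model_forward(m, X, rst, tcc, feat);
    vec yy = as<vec>(y);
    int B = X.nrow();
    vec resid = pred - yy;
    double loss = arma::dot(resid, resid) / B;
    vec dpred = 2.0 * resid / B;
    ParamMap G;
    const mat& w = m.P.at("w_out");
    G["w_out"] = mat(rowvec(dpred.t() * feat));
    G["b_out"] = mat(1, 1, arma::fill::value(arma::sum(dpred)));
    mat dfeat = dpred * w.row(0);
    if (m.arch == "transformer") tf_backward(m, X, dfeat, tcc, G);
    else rec_backward(m, dfeat, rst, G);
    // return grads in the same name order as params
    CharacterVector nm = params.names();
    List out(params.size());
    out.attr("names") = nm;
    for (int i = 0; i < params.size(); ++i) {
        std::string k = as<std::string>(nm[i]);
        const mat& g = G.at(k);
        if (Rf_isMatrix(params[i])) {
            out[i] = wrap(g);
        } else {
            out[i] = wrap(vec(g.row(0).t()));
        }
    }
    return List::create(Named("loss") = loss, Named("grads") = out);
}

// ---------------- persistent predictor handle ----------------

// A design run scores tens of thousands of single sequences; holding the
// parameters in C++ memory avoids re-marshalling them on every proposal.

// [[Rcpp::export(name = ".nn_handle")]]
SEXP nn_handle(std::string arch, List params, int nlayers, int hidden) {
    Model* m = new Model(model_from_list(arch, params, nlayers, hidden));
    XPtr<Model> ptr(m, true);
    return ptr;
}

// [[Rcpp::export(name = ".nn_predict_handle")]]
NumericVector nn_predict_handle(SEXP handle, IntegerMatrix X) {
    XPtr<Model> ptr(handle);
    RecState rst; TfCache tcc; mat feat;
    vec pred = model_forward(*ptr, X, rst, tcc, feat);
    return wrap(pred);
}
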