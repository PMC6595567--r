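phrase,label
double blind,double
double-blind,double
doubly blinded,double
double blinded,double
double dummy design,double
triple blind,double
single blind,single
single-blind,single
rater blinded,single
assessor blinded,single
open label,open
open-label,open
unblinded,open
no blinding,open
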