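ABC	ABC-like-01
ABC	ABC-like-02
ABC	ABC-like-03
ABC	ABC-like-04
ABC	ABC-like-05
ABC	ABC-like-06
ABC	ABC-like-07
ABC	ABC-like-08
ABC	ABC-like-09
ABC	ABC-like-10
ABC	ABC-like-11
ABC	ABC-like-12
ABC	ABC-like-13
ABC	ABC-like-14
ABC	ABC-like-15
ABC	ABC-like-16
ABC	ABC-like-17
ABC	ABC-like-18
ABC	ABC-like-19
ABC	ABC-like-20
ABC	ABC-like-21
ABC	ABC-like-22
ABC	ABC-like-23
ABC	ABC-like-24
ABC	ABC-like-25
ABC	ABC-like-26
ABC	ABC-like-27
ABC	ABC-like-28
ABC	ABC-like-29
ABC	ABC-like-30
GCB	GCB-like-01
GCB	GCB-like-02
GCB	GCB-like-03
GCB	GCB-like-04
GCB	GCB-like-05
GCB	GCB-like-06
GCB	GCB-like-07
GCB	GCB-like-08
GCB	GCB-like-09
GCB	GCB-like-10
GCB	GCB-like-11
GCB	GCB-like-12
GCB	GCB-like-13
GCB	GCB-like-14
GCB	GCB-like-15
GCB	GCB-like-16
GCB	GCB-like-17
GCB	GCB-like-18
GCB	GCB-like-19
GCB	GCB-like-20
GCB	GCB-like-21
GCB	GCB-like-22
GCB	GCB-like-23
GCB	GCB-like-24
GCB	GCB-like-25
GCB	GCB-like-26
GCB	GCB-like-27
GCB	GCB-like-28
GCB	GCB-like-29
GCB	GCB-like-30
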