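sample_id	sex	stage	replicate
BJ1	male	late	1
BJ2	male	late	2
BJ3	female	late	1
BJ4	female	late	2
BJ5	male	early	1
BJ6	male	early	2
BJ7	female	early	1
BJ8	female	early	2
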