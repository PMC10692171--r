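# sent_id = 30000001:0
# text = SIRT1 prevents sarcopenia.
1	SIRT1	SIRT1	NOUN	NN	_	2	nsubj	_	_
2	prevents	prevent	VERB	VBZ	_	0	root	_	_
3	sarcopenia	sarcopenia	NOUN	NN	_	2	dobj	_	_
4	.	.	PUNCT	.	_	2	punct	_	_

# sent_id = 30000001:1
# text = IL6 is associated with frailty.
1	IL6	IL6	NOUN	NN	_	3	nsubjpass	_	_
2	is	be	AUX	VBZ	_	3	auxpass	_	_
3	associated	associate	VERB	VBN	_	0	root	_	_
4	with	with	ADP	IN	_	3	prep	_	_
5	frailty	frailty	NOUN	NN	_	4	pobj	_	_
6	.	.	PUNCT	.	_	3	punct	_	_

# sent_id = 30000002:0
# text = Metformin does not prevent dementia.
1	Metformin	metformin	NOUN	NN	_	4	nsubj	_	_
2	does	do	AUX	VBZ	_	4	aux	_	_
3	not	not	PART	RB	_	4	advmod	_	_
4	prevent	prevent	VERB	VB	_	0	root	_	_
5	dementia	dementia	NOUN	NN	_	4	dobj	_	_
6	.	.	PUNCT	.	_	4	punct	_	_
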