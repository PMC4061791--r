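model_number	winner	correct	fb_rb	fb_ii
1	RB	TRUE	TRUE	FALSE
1	RB	FALSE	TRUE	FALSE
1	II	TRUE	FALSE	TRUE
1	II	FALSE	FALSE	TRUE
2	RB	TRUE	TRUE	TRUE
2	RB	FALSE	TRUE	TRUE
2	II	TRUE	TRUE	TRUE
2	II	FALSE	TRUE	TRUE
3	RB	TRUE	TRUE	TRUE
3	RB	FALSE	FALSE	FALSE
3	II	TRUE	TRUE	TRUE
3	II	FALSE	FALSE	FALSE
4	RB	TRUE	FALSE	FALSE
4	RB	FALSE	TRUE	TRUE
4	II	TRUE	FALSE	FALSE
4	II	FALSE	TRUE	TRUE
5	RB	TRUE	TRUE	TRUE
5	RB	FALSE	TRUE	TRUE
5	II	TRUE	FALSE	TRUE
5	II	FALSE	FALSE	TRUE
6	RB	TRUE	TRUE	FALSE
6	RB	FALSE	TRUE	FALSE
6	II	TRUE	TRUE	TRUE
6	II	FALSE	TRUE	TRUE
7	RB	TRUE	FALSE	TRUE
7	RB	FALSE	TRUE	TRUE
7	II	TRUE	FALSE	TRUE
7	II	FALSE	FALSE	TRUE
8	RB	TRUE	TRUE	FALSE
8	RB	FALSE	TRUE	FALSE
8	II	TRUE	TRUE	FALSE
8	II	FALSE	TRUE	TRUE
9	RB	TRUE	TRUE	FALSE
9	RB	FALSE	FALSE	FALSE
9	II	TRUE	FALSE	FALSE
9	II	FALSE	FALSE	TRUE
10	RB	TRUE	FALSE	FALSE
10	RB	FALSE	TRUE	FALSE
10	II	TRUE	FALSE	TRUE
10	II	FALSE	FALSE	FALSE
11	RB	TRUE	TRUE	FALSE
11	RB	FALSE	FALSE	FALSE
11	II	TRUE	FALSE	TRUE
11	II	FALSE	FALSE	FALSE
12	RB	TRUE	FALSE	FALSE
12	RB	FALSE	TRUE	FALSE
12	II	TRUE	FALSE	FALSE
12	II	FALSE	FALSE	TRUE
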