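cohort	grouping	group	time
rnaseq	cervical_dilatation	TNL	09:46
rnaseq	cervical_dilatation	TNL	09:56
rnaseq	cervical_dilatation	TNL	10:07
rnaseq	cervical_dilatation	TNL	10:54
rnaseq	cervical_dilatation	TNL	11:58
rnaseq	cervical_dilatation	TNL	12:25
rnaseq	cervical_dilatation	TNL	13:23
rnaseq	cervical_dilatation	TNL	13:32
rnaseq	cervical_dilatation	TEaL	01:45
rnaseq	cervical_dilatation	TEaL	06:57
rnaseq	cervical_dilatation	TEaL	15:02
rnaseq	cervical_dilatation	TEaL	15:10
rnaseq	cervical_dilatation	TEaL	18:33
rnaseq	cervical_dilatation	TEaL	20:02
rnaseq	cervical_dilatation	TEaL	20:12
rnaseq	cervical_dilatation	TEaL	22:08
rnaseq	cervical_dilatation	TEsL	06:16
rnaseq	cervical_dilatation	TEsL	07:28
rnaseq	cervical_dilatation	TEsL	10:19
rnaseq	cervical_dilatation	TEsL	11:00
rnaseq	cervical_dilatation	TEsL	12:26
rnaseq	cervical_dilatation	TEsL	23:25
rnaseq	fetal_membrane_rupture	TNL	09:46
rnaseq	fetal_membrane_rupture	TNL	09:56
rnaseq	fetal_membrane_rupture	TNL	10:07
rnaseq	fetal_membrane_rupture	TNL	10:54
rnaseq	fetal_membrane_rupture	TNL	11:58
rnaseq	fetal_membrane_rupture	TNL	12:25
rnaseq	fetal_membrane_rupture	TNL	13:23
rnaseq	fetal_membrane_rupture	TNL	13:32
rnaseq	fetal_membrane_rupture	TL-ROM	01:45
rnaseq	fetal_membrane_rupture	TL-ROM	06:16
rnaseq	fetal_membrane_rupture	TL-ROM	06:57
rnaseq	fetal_membrane_rupture	TL-ROM	07:28
rnaseq	fetal_membrane_rupture	TL-ROM	11:00
rnaseq	fetal_membrane_rupture	TL-ROM	15:10
rnaseq	fetal_membrane_rupture	TL-ROM	18:33
rnaseq	fetal_membrane_rupture	TL-ROM	20:02
rnaseq	fetal_membrane_rupture	TL+ROM	10:19
rnaseq	fetal_membrane_rupture	TL+ROM	12:26
rnaseq	fetal_membrane_rupture	TL+ROM	15:02
rnaseq	fetal_membrane_rupture	TL+ROM	20:12
rnaseq	fetal_membrane_rupture	TL+ROM	22:08
rnaseq	fetal_membrane_rupture	TL+ROM	23:25
second	cervical_dilatation	TNL	09:29
second	cervical_dilatation	TNL	09:32
second	cervical_dilatation	TNL	09:48
second	cervical_dilatation	TNL	11:15
second	cervical_dilatation	TNL	11:17
second	cervical_dilatation	TNL	11:19
second	cervical_dilatation	TNL	12:46
second	cervical_dilatation	TNL	16:39
second	cervical_dilatation	TEaL	09:13
second	cervical_dilatation	TEaL	09:29
second	cervical_dilatation	TEaL	10:10
second	cervical_dilatation	TEaL	12:44
second	cervical_dilatation	TEaL	12:57
second	cervical_dilatation	TEaL	15:26
second	cervical_dilatation	TEaL	15:31
second	cervical_dilatation	TEaL	16:03
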