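# Basic English stop words: determiners, conjunctions, prepositions,
# pronouns and auxiliaries removed before narrative scoring.
a
an
the
this
that
these
those
some
any
each
every
no
and
or
but
nor
so
yet
for
because
although
though
while
whereas
in
on
at
by
with
from
into
onto
of
off
over
under
above
below
to
up
down
out
about
between
through
during
before
after
against
i
me
my
mine
we
us
our
ours
you
your
yours
he
him
his
she
her
hers
it
its
they
them
their
theirs
who
whom
whose
which
what
is
am
are
was
were
be
been
being
have
has
had
having
do
does
did
doing
will
would
shall
should
can
could
may
might
must
not
only
also
very
just
than
then
there
here
when
where
why
how
as
if
once
all
both
few
more
most
other
such
own
same
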